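# model persistence: a directory holding metadata.txt (key=value) plus one
# long-format CSV of every numeric parameter, written at full precision
# ("%.17g") so predictions round-trip bit-identically.

fmt17 <- function(x) sprintf("%.17g", x)

mat_rows <- function(component, domain, unit, param, M) {
  M <- as.matrix(M)
  idx <- which(!is.na(M), arr.ind = TRUE)
  data.frame(component = component, domain = domain, unit = unit,
             param = param, i = idx[, 1], j = idx[, 2],
             value = fmt17(M[idx]), stringsAsFactors = FALSE)
}

mlp_rows <- function(component, domain, unit, net) {
  rbind(mat_rows(component, domain, unit, "W1", net$W1),
        mat_rows(component, domain, unit, "b1", matrix(net$b1, ncol = 1)),
        mat_rows(component, domain, unit, "W2", net$W2),
        mat_rows(component, domain, unit, "b2", matrix(net$b2)),
        mat_rows(component, domain, unit, "center", matrix(net$center, ncol = 1)),
        mat_rows(component, domain, unit, "scale", matrix(net$scale, ncol = 1)))
}

rows_to_mat <- function(rows, param) {
  r <- rows[rows$param == param, ]
  M <- matrix(0, max(r$i), max(r$j))
  M[cbind(r$i, r$j)] <- as.numeric(r$value)
  M
}

rows_to_mlp <- function(rows) {
  net <- list(W1 = rows_to_mat(rows, "W1"),
              b1 = as.numeric(rows_to_mat(rows, "b1")),
              W2 = rows_to_mat(rows, "W2"),
              b2 = as.numeric(rows_to_mat(rows, "b2")),
              center = as.numeric(rows_to_mat(rows, "center")),
              scale = as.numeric(rows_to_mat(rows, "scale")))
  net$hidden <- nrow(net$W1)
  net$d <- ncol(net$W1)
  net$epochs_run <- NA_integer_
  net$best_epoch <- NA_integer_
  class(net) <- "errp_mlp"
  net
}

#' Save / load a fitted fusion model
#'
#' `write_errp_model` persists a fitted [errp_fusion()] model as plain text:
#' a `metadata.txt` of key=value pairs (dimensions, window, seed, control
#' echo, channel labels) and a `weights.csv` holding every parameter of the
#' templates, the CSP bank and all networks in long format at full numeric
#' precision. `read_errp_model` reconstructs a model whose predictions are
#' identical to the original's.
#'
#' @param model a fitted `errp_fusion` object.
#' @param dir directory to create/write into.
#' @return `write_errp_model` returns `dir` invisibly; `read_errp_model`
#'   returns an `errp_fusion` object.
#' @export
write_errp_model <- function(model, dir) {
  stopifnot(inherits(model, "errp_fusion"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctrl <- model$control
  meta <- c(package = "errpfusion",
            version = as.character(packageVersion("errpfusion")),
            seed = model$seed, fs = model$fs,
            window_start_ms = model$window[1], window_end_ms = model$window[2],
            channel_labels = paste(model$channel_labels, collapse = ","),
            activation_hidden = "tansig", activation_output = "logsig",
            stats::setNames(unlist(ctrl[names(ctrl) != "freq_unit"]),
                            names(ctrl)[names(ctrl) != "freq_unit"]),
            freq_unit = ctrl$freq_unit)
  writeLines(paste0(names(meta), "=", meta), file.path(dir, "metadata.txt"))

  rows <- list(
    mat_rows("template", "", "positive", "M", model$templates$positive),
    mat_rows("template", "", "negative", "M", model$templates$negative),
    mat_rows("csp", "", "", "W", model$csp$W),
    mat_rows("csp", "", "", "P", model$csp$P),
    mat_rows("csp", "", "", "B", model$csp$B),
    mat_rows("csp", "", "", "U_C", model$csp$U_C),
    mat_rows("csp", "", "", "lambda_C", matrix(model$csp$lambda_C, ncol = 1)),
    mat_rows("csp", "", "", "lambda_p", matrix(model$csp$lambda_p, ncol = 1)))
  for (d in names(model$stage1))
    for (ch in names(model$stage1[[d]]))
      rows[[length(rows) + 1]] <- mlp_rows("stage1", d, ch, model$stage1[[d]][[ch]])
  for (d in names(model$stage2))
    rows[[length(rows) + 1]] <- mlp_rows("stage2", d, "", model$stage2[[d]])
  for (key in names(model$combiners))
    rows[[length(rows) + 1]] <- mlp_rows("combiner", key, "", model$combiners[[key]])
  write.csv(do.call(rbind, rows), file.path(dir, "weights.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_errp_model
#' @export
read_errp_model <- function(dir) {
  meta_lines <- readLines(file.path(dir, "metadata.txt"))
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), ""), vapply(kv, `[[`, "", 1))
  w <- read.csv(file.path(dir, "weights.csv"), stringsAsFactors = FALSE,
                colClasses = c(value = "character"))
  w$domain[is.na(w$domain)] <- ""
  w$unit[is.na(w$unit)] <- ""
  channel_labels <- strsplit(meta[["channel_labels"]], ",")[[1]]

  tpl_rows <- w[w$component == "template", ]
  templates <- structure(list(
    positive = rows_to_mat(tpl_rows[tpl_rows$unit == "positive", ], "M"),
    negative = rows_to_mat(tpl_rows[tpl_rows$unit == "negative", ], "M"),
    channel_labels = channel_labels), class = "errp_templates")
  templates$n_samples <- ncol(templates$positive)

  csp_rows <- w[w$component == "csp", ]
  lambda_p <- as.numeric(rows_to_mat(csp_rows, "lambda_p"))
  csp <- structure(list(W = rows_to_mat(csp_rows, "W"),
                        P = rows_to_mat(csp_rows, "P"),
                        B = rows_to_mat(csp_rows, "B"),
                        U_C = rows_to_mat(csp_rows, "U_C"),
                        lambda_C = as.numeric(rows_to_mat(csp_rows, "lambda_C")),
                        lambda_p = lambda_p, lambda_n = 1 - lambda_p,
                        channel_labels = channel_labels),
                   class = "errp_csp")

  net_set <- function(component) {
    rows <- w[w$component == component, ]
    doms <- unique(rows$domain)
    out <- lapply(doms, function(d) {
      dr <- rows[rows$domain == d, ]
      units <- unique(dr$unit)
      nets <- lapply(units, function(u) rows_to_mlp(dr[dr$unit == u, ]))
      names(nets) <- units
      if (identical(units, "")) nets[[1]] else nets
    })
    names(out) <- doms
    out
  }
  ctrl <- fusion_control(
    hidden_stage1 = as.integer(meta[["hidden_stage1"]]),
    hidden_stage2 = as.integer(meta[["hidden_stage2"]]),
    hidden_combiner = as.integer(meta[["hidden_combiner"]]),
    max_epochs = as.integer(meta[["max_epochs"]]),
    val_fraction = as.numeric(meta[["val_fraction"]]),
    patience = as.integer(meta[["patience"]]),
    max_lag = as.integer(meta[["max_lag"]]),
    max_imfs = as.integer(meta[["max_imfs"]]),
    keep_imfs = as.integer(meta[["keep_imfs"]]),
    freq_unit = meta[["freq_unit"]],
    class_weights = as.logical(meta[["class_weights"]]))
  structure(list(templates = templates, csp = csp,
                 stage1 = net_set("stage1"), stage2 = net_set("stage2"),
                 combiners = net_set("combiner"),
                 control = ctrl, seed = as.integer(meta[["seed"]]),
                 channel_labels = channel_labels,
                 fs = as.numeric(meta[["fs"]]),
                 window = c(as.numeric(meta[["window_start_ms"]]),
                            as.numeric(meta[["window_end_ms"]])),
                 level3_train = NULL, labels_train = NULL,
                 subjects_train = NULL, fitted_scores = NULL),
            class = "errp_fusion")
}
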