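#' The 56-channel extended 10-20 montage
#'
#' Returns the electrode table used throughout the package: the 56 scalp
#' labels of the extended international 10-20 layout in their canonical
#' front-to-back order (starting at FP1), approximate 2-D head coordinates
#' (unit head radius, nose up), and the built-in error-potential scalp weight
#' used by the synthetic-data generator. The weight is a Gaussian bump over
#' scalp distance from FCz (maximum 1 at FCz), emulating the fronto-central
#' topography of the feedback error-related negativity; no biophysical
#' forward model is involved.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `ern_weight`,
#'   one row per electrode, in montage order.
#' @examples
#' m <- errp_montage()
#' m[m$label %in% c("FCz", "Cz", "O2"), ]
#' @export
errp_montage <- function() {
  if (!is.null(.errp_env$montage)) return(.errp_env$montage)
  path <- system.file("extdata", "montage56.csv", package = "errpfusion")
  m <- read.csv(path, stringsAsFactors = FALSE)
  # fERN topography: Gaussian in scalp distance from FCz, sigma 0.4 head radii
  fcz <- m[m$label == "FCz", ]
  d2 <- (m$x - fcz$x)^2 + (m$y - fcz$y)^2
  m$ern_weight <- exp(-d2 / (2 * 0.4^2))
  .errp_env$montage <- m
  m
}

montage_weights <- function(labels) {
  m <- errp_montage()
  idx <- match(labels, m$label)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "),
         " (must come from the built-in 56-channel montage, see errp_montage())")
  }
  m$ern_weight[idx]
}
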