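#' Weighted contact number rigidity profile
#'
#' The weighted contact number (WCN) of residue k is the sum over all other
#' residues m of 1/r_km^2, where r_km is the C-alpha/C-alpha distance. High
#' WCN marks tightly packed, rigid positions; catalytic residues tend to sit
#' at such positions. WCN is computed over every residue of the processed
#' structure (side-chain vector or not), then normalized per protein to a
#' z-score with population (divide-by-n) statistics:
#' z_k = (w_k - mean(w)) / sd(w).
#'
#' The crystallographic B-factor is deliberately not used: it is absent for
#' NMR structures and varies between crystal forms of the same enzyme,
#' whereas WCN depends only on the coordinates.
#'
#' @param struct a `catres_structure` with at least 2 residues.
#' @param normalize compute the per-protein z-scores (default TRUE); with
#'   `FALSE` only the raw contact numbers are returned (`z_w` is `NA`),
#'   which is the only option for degenerate structures whose WCN variance
#'   is zero.
#' @return A `catres_flexibility`: data frame with columns `w` and `z_w`
#'   (one row per residue, aligned with `struct$residues`), carrying the
#'   protein mean and population SD as attributes `w_mean`, `w_sd`.
#' @export
wcn <- function(struct, normalize = TRUE) {
  stopifnot(inherits(struct, "catres_structure"))
  ca <- as.matrix(struct$residues[, c("ca_x", "ca_y", "ca_z")])
  n <- nrow(ca)
  if (n < 2) stop("WCN needs at least 2 residues")
  d2 <- as.matrix(stats::dist(ca))^2
  zero <- which(d2 == 0 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    ids <- residue_ids(struct)
    stop("coincident C-alpha atoms: ", ids[zero[1, 1]], " and ", ids[zero[1, 2]])
  }
  inv <- 1 / d2
  diag(inv) <- 0
  w <- rowSums(inv)
  s <- pop_sd(w)
  if (normalize && s == 0)
    stop("cannot normalize WCN: zero variance across residues")
  out <- data.frame(w = w,
                    z_w = if (normalize) (w - mean(w)) / s else NA_real_)
  attr(out, "w_mean") <- mean(w)
  attr(out, "w_sd") <- s
  class(out) <- c("catres_flexibility", "data.frame")
  out
}
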