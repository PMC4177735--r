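#' Read an NCBI PSI-BLAST ASCII PSSM
#'
#' Parses the text matrix written by `psiblast -out_ascii_pssm`. Each data
#' row carries the 1-based position, the query residue letter, 20 log-odds
#' scores, 20 weighted observed percentages, the information per position
#' (bits) and the relative weight of gapless real matches. The information
#' per position -- the conservation signal used here -- is taken as the
#' second-to-last numeric column, which is stable across NCBI versions
#' whose headers differ. Rows with fewer than 24 numeric fields raise a
#' parse error naming the line.
#'
#' @param pssm path to the ASCII PSSM, or a character vector of its lines.
#' @return A `catres_pssm`: list with `pos` (integer), `aa` (one-letter
#'   residue codes) and `info` (bits per position).
#' @export
read_pssm <- function(pssm) {
  lines <- if (length(pssm) == 1 && !grepl("\n", pssm) && file.exists(pssm))
    readLines(pssm) else unlist(strsplit(pssm, "\n"))
  pos <- integer(0); aa <- character(0); info <- numeric(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3) next
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Za-z]$", tok[2])) next
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(num) || length(num) < 22)
      stop("malformed PSSM row at line ", i, ": expected >= 24 numeric fields")
    pos <- c(pos, as.integer(tok[1]))
    aa <- c(aa, toupper(tok[2]))
    info <- c(info, num[length(num) - 1])
  }
  if (length(pos) == 0) stop("no PSSM data rows found: not an NCBI ASCII PSSM?")
  if (any(diff(pos) != 1) || pos[1] != 1)
    stop("PSSM positions are not consecutive from 1")
  if (any(info < 0)) stop("negative information-per-position value in PSSM")
  structure(list(pos = pos, aa = aa, info = info), class = "catres_pssm")
}

#' Map PSSM positions onto structure residues
#'
#' Aligns the PSSM query sequence to a chain's residue sequence. An exact
#' match is required, allowing only a constant leading/trailing offset
#' (either the structure missing terminal residues present in the PSSM, or
#' vice versa); any internal mismatch is an error. Structure residues not
#' covered by the PSSM are recorded as unmapped and later treated as
#' conservation z-score 0.
#'
#' The per-position information contents are normalized to z-scores with
#' population statistics over all PSSM positions of the chain.
#'
#' @param pssm a `catres_pssm`.
#' @param struct a `catres_structure`.
#' @param chain chain identifier to map.
#' @return A `catres_conservation`: list with `z_c` (numeric, one value per
#'   structure residue; 0 where unmapped or off-chain), `mapped` (logical
#'   per residue), `c_mean`, `c_sd`, `chain`.
#' @export
map_to_structure <- function(pssm, struct, chain) {
  stopifnot(inherits(pssm, "catres_pssm"), inherits(struct, "catres_structure"))
  ridx <- which(struct$residues$chain == chain)
  if (length(ridx) == 0) stop("chain not found in structure: ", chain)
  sseq <- unname(AA1[struct$residues$aa[ridx]])
  pseq <- pssm$aa
  ns <- length(sseq); np <- length(pseq)
  offset <- NA_integer_   # pssm position of structure residue 1, minus 1
  if (ns <= np) {
    for (k in 0:(np - ns)) {
      if (all(pseq[(k + 1):(k + ns)] == sseq)) { offset <- k; break }
    }
  }
  rev_off <- NA_integer_  # structure residue index of pssm position 1, minus 1
  if (is.na(offset) && np < ns) {
    for (k in 0:(ns - np)) {
      if (all(sseq[(k + 1):(k + np)] == pseq)) { rev_off <- k; break }
    }
  }
  if (is.na(offset) && is.na(rev_off))
    stop("PSSM sequence does not match chain ", chain,
         " (beyond a terminal offset); cannot map conservation")
  c_mean <- mean(pssm$info)
  c_sd <- pop_sd(pssm$info)
  if (c_sd == 0) warning("constant PSSM information content: all z_c set to 0")
  z_all <- if (c_sd > 0) (pssm$info - c_mean) / c_sd else rep(0, np)
  z_c <- rep(0, nrow(struct$residues))
  mapped <- rep(FALSE, nrow(struct$residues))
  if (!is.na(offset)) {
    z_c[ridx] <- z_all[offset + seq_len(ns)]
    mapped[ridx] <- TRUE
  } else {
    z_c[ridx[rev_off + seq_len(np)]] <- z_all
    mapped[ridx[rev_off + seq_len(np)]] <- TRUE
  }
  structure(list(z_c = z_c, mapped = mapped, c_mean = c_mean, c_sd = c_sd,
                 chain = chain),
            class = "catres_conservation")
}

#' Fuse sequence conservation into the structure score
#'
#' S' = S + weight * z_c, with z_c the normalized information per position
#' of the residue (0 for unmapped residues). The default weight of 1.6
#' balances the conservation term against the structure score. With weight
#' 0 or all-zero z_c, the fused ranking reduces exactly to the
#' structure-only ranking.
#'
#' @param scores a `catres_scores` data frame.
#' @param conservation a `catres_conservation` from [map_to_structure()],
#'   or a numeric vector of z_c values aligned with the structure residues.
#' @param weight conservation weight (default 1.6).
#' @return the score table with `z_cons` and `S_prime` columns added.
#' @export
fuse_scores <- function(scores, conservation, weight = 1.6) {
  z_c <- if (inherits(conservation, "catres_conservation"))
    conservation$z_c else conservation
  zc <- z_c[scores$idx]
  scores$z_cons <- zc
  scores$S_prime <- scores$S + weight * zc
  scores
}
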