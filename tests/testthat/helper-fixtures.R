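# Hand-rolled PDB line formatting, deliberately independent of the
# package's own generator so that structure-io tests do not share code with
# the code under test.
fmt_pdb_line <- function(record = "ATOM", serial = 1, name, alt = "",
                         resname, chain = "A", resno, icode = "",
                         xyz, occ = 1, bfac = 0) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf("%-4s", paste0(" ", name))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, bfac, substr(name, 1, 1))
}

# build PDB text from a residue table: list of lists with fields
# aa, resno, ca (3-vec), sv (3-vec or NULL), chain, extra backbone atoms
pdb_from_residues <- function(res, footer = c("TER", "END")) {
  serial <- 0
  lines <- character(0)
  for (r in res) {
    chain <- if (is.null(r$chain)) "A" else r$chain
    if (is.null(r$skip_n)) {
      serial <- serial + 1
      lines <- c(lines, fmt_pdb_line(serial = serial, name = "N", resname = r$aa,
                                     chain = chain, resno = r$resno,
                                     xyz = r$ca + c(-1, 0.5, 0)))
    }
    if (is.null(r$skip_ca)) {
      serial <- serial + 1
      lines <- c(lines, fmt_pdb_line(serial = serial, name = "CA", resname = r$aa,
                                     chain = chain, resno = r$resno, xyz = r$ca))
    }
    if (!is.null(r$sv)) {
      va <- r$sv_name
      if (is.null(va)) va <- catres::sidechain_vector_atom(r$aa)
      serial <- serial + 1
      lines <- c(lines, fmt_pdb_line(serial = serial, name = va, resname = r$aa,
                                     chain = chain, resno = r$resno, xyz = r$sv))
    }
  }
  paste(c(lines, footer), collapse = "\n")
}

# random protein-like blob: n residues on a jittered grid, random types,
# side-chain vectors in random directions
random_blob_pdb <- function(n = 50, seed = 1, spread = 25) {
  set.seed(seed)
  types <- sample(c(names(catres:::SIDECHAIN_VECTOR_ATOMS), "GLY", "ALA"),
                  n, replace = TRUE)
  res <- list()
  pts <- matrix(runif(n * 3, 0, spread), ncol = 3)
  # enforce minimal separation by jittered lattice assignment
  for (i in seq_len(n)) {
    ca <- pts[i, ]
    sv <- NULL
    if (types[i] %in% names(catres:::SIDECHAIN_VECTOR_ATOMS)) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      sv <- ca + 2.2 * d
    }
    res[[i]] <- list(aa = types[i], resno = i, ca = ca, sv = sv)
  }
  pdb_from_residues(res)
}

# synthetic NCBI ASCII PSSM text for a given one-letter sequence and
# information-per-position vector
pssm_text <- function(seq1, info, weight = NULL) {
  stopifnot(length(seq1) == length(info))
  if (is.null(weight)) weight <- rep(0.1, length(info))
  aa_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(rep(aa_order, 2), collapse = "   "))
  )
  rows <- vapply(seq_along(seq1), function(i) {
    scores <- sample(-5:8, 20, replace = TRUE)
    pct <- sample(0:100, 20, replace = TRUE)
    paste0(sprintf("%5d %s  ", i, seq1[i]),
           paste(sprintf("%3d", scores), collapse = " "), "  ",
           paste(sprintf("%3d", pct), collapse = " "),
           sprintf("  %5.2f %9.2f", info[i], weight[i]))
  }, "")
  paste(c(header, rows, "", "                      K         Lambda"), collapse = "\n")
}

# build a minimal catres_candidates object from explicit surrounding sets
manual_candidates <- function(surrounding, points = NULL) {
  m <- length(surrounding)
  if (is.null(points)) points <- matrix(0, nrow = m, ncol = 3)
  structure(list(points = points, surrounding = surrounding,
                 theta = rep(list(numeric(0)), m),
                 mean_theta = rep(0, m), radius = 10, theta_cutoff = 80,
                 min_surrounding = 3, n_grid = m, n_after_min = m,
                 n_after_theta = m),
            class = "catres_candidates")
}

# Mann-Whitney formulation of the AUC: fraction of (positive, negative)
# pairs ranked correctly, ties counted half
mann_whitney_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
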