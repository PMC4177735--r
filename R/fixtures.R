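# Synthetic test structures: a planted "catalytic site" whose side chains
# point at a common center, among decoy residues with random (or outward)
# side-chain directions. These emulate the one geometric signal the scoring
# method reads -- concerted inward side-chain orientation plus local
# packing -- and nothing else about real proteins (no backbone continuity,
# no rotamer realism, no solvent).

#' Specification of a synthetic planted-site structure
#'
#' @param n_site number of site residues (>= 3) placed on a ring.
#' @param site_aa 3-letter codes for the site residues (recycled); must be
#'   vector-bearing types.
#' @param ring_radius ring radius in Angstrom (> 0); site C-alphas sit on
#'   this ring around the site center.
#' @param displacement side-chain vector-atom displacement in Angstrom;
#'   positive points toward the ring center, negative away from it.
#' @param jitter_deg random angular jitter (degrees, SD) applied to site
#'   side-chain directions.
#' @param n_decoys number of decoy residues scattered outside the site.
#' @param decoy_shell inner/outer radius (Angstrom) of the decoy shell. The
#'   default starts at ring_radius + 10 so that no decoy can be a
#'   surrounding residue of the planted center itself.
#' @param decoy_max_neighbors placement cap: a decoy position is rejected
#'   while more than this many already-placed residues lie within 10
#'   Angstrom of it (default 1). Decoys are meant to be isolated background
#'   residues with random orientations; without the cap, random placement
#'   occasionally condenses decoys into clusters as tight as the planted
#'   ring, which would plant a second, unlabeled site.
#' @param decoy_mode `"random"` (random side-chain directions) or
#'   `"outward"` (pointing away from the structure center).
#' @param seed integer random seed; the generated PDB text is a pure
#'   function of the spec, byte-identical for equal seeds.
#' @return a `catres_toyspec` list.
#' @export
toy_site_spec <- function(n_site = 3, site_aa = c("HIS", "ASP", "GLU"),
                          ring_radius = 4, displacement = 2.4,
                          jitter_deg = 8, n_decoys = 25,
                          decoy_shell = c(14, 28), decoy_max_neighbors = 1,
                          decoy_mode = c("random", "outward"), seed = 1) {
  decoy_mode <- match.arg(decoy_mode)
  stopifnot(n_site >= 3, ring_radius > 0, n_decoys >= 0,
            length(decoy_shell) == 2, decoy_shell[1] > ring_radius,
            decoy_max_neighbors >= 0)
  site_aa <- toupper(rep_len(site_aa, n_site))
  if (!all(site_aa %in% names(SIDECHAIN_VECTOR_ATOMS)))
    stop("site_aa must be drawn from the 12 vector-bearing types")
  structure(list(n_site = n_site, site_aa = site_aa, ring_radius = ring_radius,
                 displacement = displacement, jitter_deg = jitter_deg,
                 n_decoys = n_decoys, decoy_shell = decoy_shell,
                 decoy_max_neighbors = decoy_max_neighbors,
                 decoy_mode = decoy_mode, seed = as.integer(seed)),
            class = "catres_toyspec")
}

# rotate unit vector u by a random small angle (sd_deg) about a random axis
jitter_direction <- function(u, sd_deg) {
  if (sd_deg <= 0) return(u)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, 0, sd_deg) * pi / 180
  # Rodrigues rotation
  u * cos(ang) + c(ax[2] * u[3] - ax[3] * u[2],
                   ax[3] * u[1] - ax[1] * u[3],
                   ax[1] * u[2] - ax[2] * u[1]) * sin(ang) +
    ax * sum(ax * u) * (1 - cos(ang))
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  el <- substr(name, 1, 1)
  # one-character elements: name starts in column 14
  name4 <- sprintf("%-4s", paste0(" ", name))
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resname, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, el)
}

#' Generate a synthetic planted-site PDB
#'
#' Site residues have their C-alpha on a ring about the origin and their
#' designated side-chain vector atom displaced toward (displacement > 0) or
#' away from (displacement < 0) the ring center, with small angular jitter.
#' Decoys are scattered in a spherical shell outside the site with random
#' or outward side-chain directions. Dummy N, C, O atoms accompany each
#' C-alpha for format validity only. Output is deterministic for a fixed
#' seed.
#'
#' @param spec a `catres_toyspec` from [toy_site_spec()].
#' @return PDB text as a single string. Attribute `site_resno` gives the
#'   residue numbers of the planted site residues (chain A).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "catres_toyspec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  decoy_pool <- c(names(SIDECHAIN_VECTOR_ATOMS), "GLY", "ALA")
  ca <- list(); sv <- list(); aa <- character(0)
  # planted site: ring in a randomly oriented plane through the origin
  u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
  tmp <- rnorm(3); u2 <- tmp - sum(tmp * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  ang0 <- runif(1, 0, 2 * pi)
  for (i in seq_len(spec$n_site)) {
    a <- ang0 + 2 * pi * (i - 1) / spec$n_site
    pos <- spec$ring_radius * (cos(a) * u1 + sin(a) * u2)
    dirc <- -pos / sqrt(sum(pos^2))          # toward ring center
    dirc <- jitter_direction(dirc, spec$jitter_deg)
    ca[[length(ca) + 1]] <- pos
    sv[[length(sv) + 1]] <- pos + dirc * spec$displacement
    aa <- c(aa, spec$site_aa[i])
  }
  # decoys: rejection-sampled in the shell with minimum spacing from every
  # already-placed C-alpha and vector atom; 6 A approximates the spatial
  # neighbor distance of surface residues and keeps the planted ring the
  # tightest (most rigid) cluster in the structure, which is the fixture's
  # premise
  min_sep_ca <- 6.0
  min_sep_sv <- 4.0
  tries <- 0
  while (length(ca) < spec$n_site + spec$n_decoys) {
    tries <- tries + 1
    if (tries > 20000) stop("infeasible geometry: cannot place decoys without overlap")
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    r <- runif(1, spec$decoy_shell[1], spec$decoy_shell[2])
    pos <- d * r
    typ <- sample(decoy_pool, 1)
    dirc <- switch(spec$decoy_mode,
                   random = { v <- rnorm(3); v / sqrt(sum(v^2)) },
                   outward = pos / sqrt(sum(pos^2)))
    svpos <- pos + dirc * abs(spec$displacement)
    centers <- rbind(do.call(rbind, ca), do.call(rbind, sv))
    dca <- sqrt(rowSums((centers - rep(pos, each = nrow(centers)))^2))
    dsv <- sqrt(rowSums((centers - rep(svpos, each = nrow(centers)))^2))
    if (min(dca) < min_sep_ca || min(dsv) < min_sep_sv) next
    # keep decoys isolated: no spontaneous clusters rivaling the site
    ca_mat <- do.call(rbind, ca)
    d_ca <- sqrt(rowSums((ca_mat - rep(pos, each = nrow(ca_mat)))^2))
    if (sum(d_ca < 10) > spec$decoy_max_neighbors) next
    ca[[length(ca) + 1]] <- pos
    sv[[length(sv) + 1]] <- svpos
    aa <- c(aa, typ)
  }
  # overlap guard across all emitted atoms
  allpos <- rbind(do.call(rbind, ca), do.call(rbind, sv))
  if (min(stats::dist(allpos)) < 0.5)
    stop("infeasible geometry: overlapping atoms in generated structure")

  lines <- character(0)
  serial <- 0
  for (i in seq_along(ca)) {
    p <- ca[[i]]
    for (at in list(c("N", -1.0, 0.6, 0), c("CA", 0, 0, 0),
                    c("C", 1.0, 0.6, 0), c("O", 1.5, 1.2, 0.4))) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, at[1], aa[i], "A", i,
                                      p + as.numeric(at[2:4])))
    }
    va <- sidechain_vector_atom(aa[i])
    if (!is.na(va)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, va, aa[i], "A", i, sv[[i]]))
    }
  }
  out <- paste(c(lines, "TER", "END"), collapse = "\n")
  attr(out, "site_resno") <- seq_len(spec$n_site)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
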