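#' Read a catalytic-site annotation table
#'
#' Tab-separated file in the style of Catalytic Site Atlas entry dumps:
#' columns `structure_id  chain  resnum  icode  site_id` and (optionally)
#' `aa`, the residue's 3-letter type. Lines starting with `#` are comments.
#' The `aa` column is needed when the table is used to build co-occurrence
#' profiles; evaluation against ground-truth labels works without it.
#'
#' @param path file path.
#' @return data frame with columns `structure_id`, `chain`, `resnum`,
#'   `icode`, `site_id` and, when present, `aa`.
#' @export
read_site_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 5) stop("annotation TSV needs at least 5 columns ",
                         "(structure_id chain resnum icode site_id)")
  names(df)[1:5] <- c("structure_id", "chain", "resnum", "icode", "site_id")
  if (ncol(df) >= 6) names(df)[6] <- "aa"
  df$resnum <- as.integer(df$resnum)
  df$icode[is.na(df$icode)] <- ""
  if ("aa" %in% names(df)) df$aa <- toupper(df$aa)
  df
}

#' Build amino-acid co-occurrence profiles from catalytic-site annotations
#'
#' For each amino-acid type x, the profile p_x gives the frequency with
#' which each type y occurs in the same catalytic site as x. Two residues
#' co-occur when they are annotated in the same site (same `structure_id`
#' and `site_id`). Counting is per residue instance over all unordered
#' residue pairs of a site, in both directions (a residue never pairs with
#' itself); counts are then row-normalized to frequencies. Sites with fewer
#' than two residues contribute nothing.
#'
#' @param annotations data frame from [read_site_annotations()] (must carry
#'   the `aa` column), or a path to such a TSV.
#' @return A `catres_profiles`: 20 x 20 numeric matrix with 3-letter row and
#'   column names; row x is the profile p_x. Attribute `provenance`
#'   describes the source.
#' @export
build_profiles <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_site_annotations(annotations)
  if (!"aa" %in% names(annotations))
    stop("annotation table has no 'aa' column; residue types are required ",
         "to build co-occurrence profiles")
  bad <- !annotations$aa %in% AA3
  if (any(bad)) stop("unknown amino-acid code(s) in annotations: ",
                     paste(unique(annotations$aa[bad]), collapse = ", "))
  counts <- matrix(0, 20, 20, dimnames = list(AA3, AA3))
  sites <- split(annotations$aa,
                 paste(annotations$structure_id, annotations$site_id, sep = "\r"))
  any_pair <- FALSE
  for (aa in sites) {
    k <- length(aa)
    if (k < 2) next
    any_pair <- TRUE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        counts[aa[i], aa[j]] <- counts[aa[i], aa[j]] + 1
        counts[aa[j], aa[i]] <- counts[aa[j], aa[i]] + 1
      }
    }
  }
  if (!any_pair) stop("no catalytic site with >= 2 residues; cannot build profiles")
  rs <- rowSums(counts)
  p <- counts
  nz <- rs > 0
  p[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  attr(p, "provenance") <- sprintf("built from %d sites (%d with >= 2 residues)",
                                   length(sites), sum(lengths(sites) >= 2))
  class(p) <- c("catres_profiles", class(p))
  p
}

#' Default co-occurrence profiles
#'
#' Profiles rebuilt at call time from the synthetic catalytic-site
#' annotation table shipped with the package
#' (`inst/extdata/synthetic_catalytic_sites.tsv`), which encodes textbook
#' catalytic chemistries (Ser-His-Asp triads, carboxylate pairs, metal-His
#' clusters, ...). It is a synthetic stand-in: for production use, rebuild
#' from a real Catalytic Site Atlas dump with [build_profiles()].
#'
#' @return a `catres_profiles` matrix.
#' @export
default_profiles <- function() {
  path <- system.file("extdata", "synthetic_catalytic_sites.tsv",
                      package = "catres", mustWork = TRUE)
  build_profiles(path)
}

#' Amino-acid combination score of a triplet member
#'
#' For a residue of type x grouped with two residues of types y and z, the
#' combination score is a = p_x\[y\] + p_x\[z\], read from x's profile row
#' (asymmetric: each triplet member is scored from its own row).
#'
#' @param x,y,z 3-letter amino-acid codes; `x` is the scored residue's type.
#' @param profiles a `catres_profiles` matrix.
#' @return numeric score in \[0, 2\].
#' @export
combination_score <- function(x, y, z, profiles) {
  profiles[x, y] + profiles[x, z]
}

#' Normalize combination scores over a protein
#'
#' z_a = (a - mean(a)) / sd(a) with population statistics over the full
#' multiset of combination scores evaluated for the protein (one value per
#' residue-in-triplet occurrence). If all scores are identical (zero SD),
#' every z_a is set to 0 with a warning.
#'
#' @param a numeric vector of combination scores.
#' @return numeric vector of z-scores, same length.
#' @export
normalize_combination <- function(a) {
  s <- pop_sd(a)
  if (s == 0) {
    warning("constant combination scores: all z_a set to 0")
    return(rep(0, length(a)))
  }
  (a - mean(a)) / s
}

#' Write / read a profile matrix as TSV
#'
#' 20 x 20 tab-separated matrix with 3-letter-code row and column headers.
#'
#' @param profiles a `catres_profiles` matrix.
#' @param path file path.
#' @return `read_profiles` returns a `catres_profiles` matrix;
#'   `write_profiles` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  m <- as.matrix(unclass(profiles))
  utils::write.table(format(m, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (!identical(sort(rownames(m)), sort(AA3)))
    stop("profile TSV must have the 20 standard 3-letter codes as row names")
  m <- m[AA3, AA3]
  attr(m, "provenance") <- paste("loaded from", path)
  class(m) <- c("catres_profiles", class(m))
  m
}
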