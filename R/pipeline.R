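#' Predict catalytic residues of a structure
#'
#' Runs the full pipeline: read PDB, strip nonprotein content, embed in the
#' scanning grid, select candidate site centers, compute WCN rigidity,
#' accumulate triplet feature scores, optionally fuse PSI-BLAST sequence
#' conservation, and rank. Stage counts are reported via `message()` when
#' `verbose = TRUE`.
#'
#' @param pdb path to a PDB file, a character vector of PDB lines, or a
#'   `catres_structure`.
#' @param chains optional chain filter (default: all protein chains).
#' @param profiles a `catres_profiles` matrix, or a path to a profile TSV;
#'   default [default_profiles()].
#' @param pssm optional PSI-BLAST ASCII PSSM (path or text) for one chain.
#' @param pssm_chain chain the PSSM belongs to; defaults to the first chain.
#' @param cons_weight conservation fusion weight (default 1.6).
#' @param grid_points grid points per axis (default 30).
#' @param radius surrounding-residue cutoff, Angstrom (default 10).
#' @param theta_cutoff mean-angle cutoff, degrees (default 80).
#' @param min_surrounding minimum surrounding residues per point (default 3).
#' @param max_residues size guard; structures with more residues are
#'   refused (default 5000).
#' @param method `"fast"` (closed-form accumulation) or `"bruteforce"`
#'   (explicit triplet enumeration; reference oracle, small inputs only).
#' @param verbose log stage counts to stderr (default FALSE).
#' @return A `catres_prediction`: list with `scores` (ranked data frame
#'   with a `rank` column), `backbone` (auxiliary report for the 8
#'   non-vector types), `structure`, `candidates`, `flexibility`, and
#'   `params`.
#' @examples
#' pdb <- make_toy_structure(toy_site_spec(seed = 42))
#' pred <- predict_catalytic_residues(pdb)
#' head(pred$scores)
#' @export
predict_catalytic_residues <- function(pdb, chains = NULL,
                                       profiles = default_profiles(),
                                       pssm = NULL, pssm_chain = NULL,
                                       cons_weight = 1.6,
                                       grid_points = 30, radius = 10,
                                       theta_cutoff = 80, min_surrounding = 3,
                                       max_residues = 5000,
                                       method = c("fast", "bruteforce"),
                                       verbose = FALSE) {
  method <- match.arg(method)
  say <- function(...) if (verbose) message("[catres] ", ...)
  struct <- if (inherits(pdb, "catres_structure")) pdb else read_structure(pdb, chains)
  struct <- strip_nonprotein(struct)
  n_res <- nrow(struct$residues)
  if (n_res == 0) stop("no protein residues left after stripping")
  if (n_res > max_residues)
    stop("structure has ", n_res, " residues, above the limit of ", max_residues,
         "; raise max_residues to override")
  say(n_res, " protein residues kept (", sum(struct$residues$has_sv),
      " with side-chain vectors)")
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  grid <- build_grid(struct, n_points = grid_points)
  cand <- candidate_points(struct, grid, radius = radius,
                           theta_cutoff = theta_cutoff,
                           min_surrounding = min_surrounding)
  say(cand$n_grid, " grid points; ", cand$n_after_min, " with >= ",
      min_surrounding, " surrounding residues; ", cand$n_after_theta,
      " after mean-theta filter")
  flex <- wcn(struct)
  scores <- if (method == "fast")
    accumulate_scores_fast(struct, cand, flex, profiles)
  else
    accumulate_scores_bruteforce(struct, cand, flex, profiles)
  say(sum(scores$triplet_count), " triplet memberships accumulated over ",
      nrow(scores), " rankable residues")
  cons <- NULL
  if (!is.null(pssm)) {
    pobj <- if (inherits(pssm, "catres_pssm")) pssm else read_pssm(pssm)
    if (is.null(pssm_chain)) pssm_chain <- struct$residues$chain[1]
    cons <- map_to_structure(pobj, struct, pssm_chain)
    scores <- fuse_scores(scores, cons, weight = cons_weight)
    say("conservation fused for chain ", pssm_chain, " (weight ", cons_weight, ")")
  }
  ranked <- rank_residues(scores)
  structure(list(scores = ranked,
                 backbone = backbone_report(struct, flex, profiles),
                 structure = struct, candidates = cand, flexibility = flex,
                 conservation = cons,
                 params = list(grid_points = grid_points, radius = radius,
                               theta_cutoff = theta_cutoff,
                               min_surrounding = min_surrounding,
                               cons_weight = cons_weight, method = method)),
            class = "catres_prediction")
}

#' @export
print.catres_prediction <- function(x, ...) {
  cat("<catres_prediction> ", x$structure$id, ": ", nrow(x$scores),
      " ranked residues", if (!is.null(x$conservation)) " (conservation fused)",
      "\n", sep = "")
  print(utils::head(x$scores[, setdiff(names(x$scores), "idx")], 5))
  invisible(x)
}

#' Write a ranked prediction as TSV
#'
#' Columns: `rank`, `chain`, `resnum`, `icode`, `aa`, `S`, `S_prime`,
#' `triplet_count`, `z_wcn`, `mean_z_a`, `z_cons`. `S_prime` and `z_cons`
#' are empty when no PSSM was fused.
#'
#' @param pred a `catres_prediction` (or its ranked `scores` data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  sc <- if (inherits(pred, "catres_prediction")) pred$scores else pred
  out <- data.frame(rank = sc$rank, chain = sc$chain, resnum = sc$resno,
                    icode = sc$icode, aa = sc$aa, S = sc$S,
                    S_prime = if ("S_prime" %in% names(sc)) sc$S_prime else NA_real_,
                    triplet_count = sc$triplet_count, z_wcn = sc$z_wcn,
                    mean_z_a = sc$mean_z_a,
                    z_cons = if ("z_cons" %in% names(sc)) sc$z_cons else NA_real_,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path file path.
#' @return data frame in `catres_scores` column layout (with `rank`).
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(icode = "character", chain = "character"))
  df$icode[is.na(df$icode)] <- ""
  names(df)[names(df) == "resnum"] <- "resno"
  df
}
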