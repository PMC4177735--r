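#' Side-chain vector atom for an amino-acid type
#'
#' Returns the PDB name of the designated functional side-chain atom used
#' as the tip of the side-chain direction vector. Vector atoms are defined
#' only for the 12 amino-acid types whose functional atom normally sits on
#' the side chain: ARG (CZ), ASN (CG), ASP (CG), CYS (SG), GLN (CD),
#' GLU (CD), HIS (NE2), LYS (NZ), SER (OG), THR (OG1), TRP (CZ2), TYR (OH).
#' The remaining 8 types (backbone-functional or apolar) have none.
#'
#' @param aa three-letter residue code (case-insensitive), e.g. `"ASP"`.
#' @return The atom name as a string, or `NA_character_` for the 8 types
#'   without a designated side-chain vector atom.
#' @examples
#' sidechain_vector_atom("ASP")  # "CG"
#' sidechain_vector_atom("GLY")  # NA
#' @export
sidechain_vector_atom <- function(aa) {
  aa <- toupper(aa)
  if (!aa %in% AA3) stop("unknown amino-acid type: ", aa)
  if (aa %in% names(SIDECHAIN_VECTOR_ATOMS)) SIDECHAIN_VECTOR_ATOMS[[aa]] else NA_character_
}

new_structure <- function(id, residues, dropped_no_ca = 0L) {
  structure(
    list(id = id, residues = residues, dropped_no_ca = as.integer(dropped_no_ca)),
    class = "catres_structure"
  )
}

#' @export
print.catres_structure <- function(x, ...) {
  cat("<catres_structure> ", x$id, ": ", nrow(x$residues), " residues, ",
      sum(x$residues$has_sv), " with side-chain vector atoms, chains ",
      paste(unique(x$residues$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read a PDB structure
#'
#' Parses a PDB file into a per-residue model. Only the first model of a
#' multi-model (e.g. NMR) file is used. Alternate locations are resolved to
#' the conformer with the highest occupancy (ties: altloc `"A"`, else first
#' seen). Any residue group without a C-alpha atom is dropped; drops of
#' standard amino-acid residues are counted in `dropped_no_ca` and warned
#' about. Nonprotein groups (waters, ligands, ions) that survive because
#' they carry an atom named CA are removed by [strip_nonprotein()], which
#' should normally be called next.
#'
#' Each retained residue records its C-alpha position and, when the residue
#' type has a designated side-chain vector atom that is present in the file,
#' that atom's position (`has_sv = TRUE`).
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chains optional character vector of chain identifiers to keep.
#' @return A `catres_structure`: list with `id`, `residues` (a data frame
#'   with columns `record`, `chain`, `resno`, `icode`, `aa`, `ca_x/y/z`,
#'   `sv_x/y/z`, `has_sv`) and `dropped_no_ca`.
#' @seealso [strip_nonprotein()], [sidechain_vector_atom()]
#' @export
read_structure <- function(pdb, chains = NULL) {
  path <- pdb
  tmp <- NULL
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^(ATOM|HETATM|MODEL|HEADER)", pdb[1])) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], tmp)
    path <- tmp
    on.exit(unlink(tmp))
  }
  pdbobj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e))
  )
  at <- pdbobj$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms found in PDB input")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in selected chains")

  # resolve altlocs: within one (residue, atom name) keep highest occupancy;
  # ties go to altloc 'A', then first seen
  reskey <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
  atomkey <- paste(reskey, at$elety, sep = "\r")
  ord <- order(factor(atomkey, levels = unique(atomkey)), -at$o,
               at$alt != "A" & at$alt != "", seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$insert, sep = "\r")))), ,
           drop = FALSE]

  reskey <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
  groups <- split(seq_len(nrow(at)), factor(reskey, levels = unique(reskey)))

  n <- length(groups)
  res <- data.frame(
    record = character(n), chain = character(n), resno = integer(n),
    icode = character(n), aa = character(n),
    ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
    sv_x = NA_real_, sv_y = NA_real_, sv_z = NA_real_,
    has_sv = FALSE, stringsAsFactors = FALSE
  )
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    first <- idx[1]
    res$record[g] <- at$type[first]
    res$chain[g] <- at$chain[first]
    res$resno[g] <- at$resno[first]
    res$icode[g] <- at$insert[first]
    res$aa[g] <- at$resid[first]
    ca <- idx[at$elety[idx] == "CA"]
    if (length(ca)) {
      res$ca_x[g] <- at$x[ca[1]]; res$ca_y[g] <- at$y[ca[1]]; res$ca_z[g] <- at$z[ca[1]]
    }
    va <- if (res$aa[g] %in% names(SIDECHAIN_VECTOR_ATOMS))
      SIDECHAIN_VECTOR_ATOMS[[res$aa[g]]] else NA_character_
    if (!is.na(va)) {
      sv <- idx[at$elety[idx] == va]
      if (length(sv)) {
        res$sv_x[g] <- at$x[sv[1]]; res$sv_y[g] <- at$y[sv[1]]; res$sv_z[g] <- at$z[sv[1]]
        res$has_sv[g] <- TRUE
      }
    }
  }

  has_ca <- !is.na(res$ca_x)
  dropped_aa <- sum(!has_ca & res$aa %in% AA3)
  if (dropped_aa > 0)
    warning(dropped_aa, " amino-acid residue(s) without a C-alpha atom dropped")
  res <- res[has_ca, , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) == 0 || !any(res$aa %in% c(AA3, "MSE")))
    stop("no usable protein residues (with C-alpha) in input")
  if (any(!is.finite(as.matrix(res[, c("ca_x", "ca_y", "ca_z")]))))
    stop("non-finite C-alpha coordinates in input")

  id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(if (is.null(tmp)) path else "structure"))
  new_structure(id, res, dropped_no_ca = dropped_aa)
}

#' Remove nonprotein content from a structure
#'
#' Drops waters, ions, ligands and any other residue group whose type is not
#' one of the 20 standard amino acids. Selenomethionine (MSE) is kept and
#' mapped to MET; like MET it carries no side-chain vector atom. This mirrors
#' the preprocessing step in which all nonprotein ligands are removed before
#' grid scanning, so that only protein geometry defines candidate sites.
#'
#' @param struct a `catres_structure` from [read_structure()].
#' @return The structure with only standard amino-acid residues retained.
#' @export
strip_nonprotein <- function(struct) {
  stopifnot(inherits(struct, "catres_structure"))
  res <- struct$residues
  is_mse <- res$aa == "MSE"
  if (any(is_mse)) {
    res$aa[is_mse] <- "MET"
    res$sv_x[is_mse] <- NA_real_; res$sv_y[is_mse] <- NA_real_; res$sv_z[is_mse] <- NA_real_
    res$has_sv[is_mse] <- FALSE
  }
  res <- res[res$aa %in% AA3, , drop = FALSE]
  rownames(res) <- NULL
  struct$residues <- res
  struct
}

#' Residue identifier labels
#'
#' Compact residue labels such as `"A:123"` or `"A:123A"` (chain, PDB
#' residue number, insertion code), matching deposited numbering so ranks
#' can be cited against the literature.
#'
#' @param struct a `catres_structure`.
#' @return character vector, one label per residue.
#' @export
residue_ids <- function(struct) {
  r <- struct$residues
  paste0(ifelse(r$chain == "", "_", r$chain), ":", r$resno, r$icode)
}

# one-letter sequence of a chain, in file order
chain_sequence <- function(struct, chain) {
  r <- struct$residues[struct$residues$chain == chain, , drop = FALSE]
  if (nrow(r) == 0) stop("chain not found in structure: ", chain)
  unname(AA1[r$aa])
}
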