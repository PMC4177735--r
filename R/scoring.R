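# Per-point, per-residue structure scores.
#
# For each surviving candidate point with N surrounding residues, all C(N,3)
# triplets are enumerated (conceptually); each member j of a triplet
# receives w_n + z_w[j] + z_a[j], where w_n is the mean z_w of the three
# members and z_a is the protein-normalized amino-acid combination score.
# A residue's structure score S is the sum over every triplet of every
# candidate point that includes it.

#' Feature scores of one triplet
#'
#' Each of the three residues receives w_n + z_w + z_a, where w_n is the
#' mean normalized WCN of the triplet and z_w, z_a are the residue's own
#' normalized WCN and combination scores.
#'
#' @param z_w numeric length-3: normalized WCN of the members.
#' @param z_a numeric length-3: normalized combination scores of the members.
#' @return numeric length-3 vector of per-member feature scores.
#' @export
score_triplet <- function(z_w, z_a) {
  stopifnot(length(z_w) == 3, length(z_a) == 3)
  mean(z_w) + z_w + z_a
}

# shared scaffolding: per-candidate-point member indices, z_w values and
# profile sub-matrices; returns NULL-safe list
point_context <- function(struct, candidates, flex, profiles) {
  aa <- struct$residues$aa
  ctx <- lapply(seq_along(candidates$surrounding), function(i) {
    idx <- candidates$surrounding[[i]]
    M <- profiles[aa[idx], aa[idx], drop = FALSE]
    list(idx = idx, z_w = flex$z_w[idx], M = unclass(M))
  })
  # points with fewer than three members admit no triplet
  Filter(function(cx) length(cx$idx) >= 3, ctx)
}

empty_scores <- function(struct) {
  r <- struct$residues
  keep <- which(r$has_sv)
  data.frame(idx = keep, chain = r$chain[keep], resno = r$resno[keep],
             icode = r$icode[keep], aa = r$aa[keep],
             S = 0, triplet_count = 0L, z_wcn = NA_real_,
             mean_z_a = NA_real_, stringsAsFactors = FALSE)
}

finalize_scores <- function(struct, flex, S, count, a_sum, a_mean, a_sd) {
  out <- empty_scores(struct)
  out$S <- S[out$idx]
  out$triplet_count <- as.integer(round(count[out$idx]))
  out$z_wcn <- flex$z_w[out$idx]
  mz <- rep(NA_real_, nrow(out))
  scored <- out$triplet_count > 0
  if (a_sd > 0) {
    mz[scored] <- (a_sum[out$idx[scored]] / out$triplet_count[scored] - a_mean) / a_sd
  } else {
    mz[scored] <- 0
  }
  out$mean_z_a <- mz
  attr(out, "a_mean") <- a_mean
  attr(out, "a_sd") <- a_sd
  class(out) <- c("catres_scores", "data.frame")
  out
}

#' Accumulate structure scores by brute-force triplet enumeration
#'
#' Reference implementation: explicitly iterates every C(N,3) triplet of
#' every candidate point, in two passes (first to collect the protein-wide
#' multiset of combination scores for normalization, then to accumulate
#' feature scores). Exact but only practical for small structures; the
#' production path is [accumulate_scores_fast()], which must agree with
#' this oracle to numerical precision.
#'
#' @param struct a `catres_structure`.
#' @param candidates a `catres_candidates` from [candidate_points()].
#' @param flex a `catres_flexibility` from [wcn()].
#' @param profiles a `catres_profiles` matrix.
#' @return A `catres_scores` data frame: one row per vector-bearing residue
#'   with columns `idx`, `chain`, `resno`, `icode`, `aa`, `S`,
#'   `triplet_count`, `z_wcn`, `mean_z_a`; attributes `a_mean`, `a_sd`.
#' @export
accumulate_scores_bruteforce <- function(struct, candidates, flex, profiles) {
  n <- nrow(struct$residues)
  ctx <- point_context(struct, candidates, flex, profiles)
  # pass 1: multiset of per-membership combination scores
  a_all <- numeric(0)
  trips <- list()
  for (k in seq_along(ctx)) {
    cx <- ctx[[k]]
    N <- length(cx$idx)
    tr <- utils::combn(N, 3)
    trips[[k]] <- tr
    a_pt <- apply(tr, 2, function(t) {
      c(cx$M[t[1], t[2]] + cx$M[t[1], t[3]],
        cx$M[t[2], t[1]] + cx$M[t[2], t[3]],
        cx$M[t[3], t[1]] + cx$M[t[3], t[2]])
    })
    a_all <- c(a_all, as.numeric(a_pt))
  }
  a_mean <- if (length(a_all)) mean(a_all) else 0
  a_sd <- if (length(a_all)) pop_sd(a_all) else 0
  # guard against cancellation noise when the multiset is constant
  if (a_sd < 1e-8 * (1 + abs(a_mean))) a_sd <- 0
  if (length(a_all) && a_sd == 0)
    warning("constant combination scores: all z_a set to 0")
  S <- numeric(n); count <- integer(n); a_sum <- numeric(n)
  for (k in seq_along(ctx)) {
    cx <- ctx[[k]]
    tr <- trips[[k]]
    for (col in seq_len(ncol(tr))) {
      t <- tr[, col]
      idx3 <- cx$idx[t]
      zw3 <- cx$z_w[t]
      a3 <- c(cx$M[t[1], t[2]] + cx$M[t[1], t[3]],
              cx$M[t[2], t[1]] + cx$M[t[2], t[3]],
              cx$M[t[3], t[1]] + cx$M[t[3], t[2]])
      za3 <- if (a_sd > 0) (a3 - a_mean) / a_sd else rep(0, 3)
      S[idx3] <- S[idx3] + score_triplet(zw3, za3)
      count[idx3] <- count[idx3] + 1L
      a_sum[idx3] <- a_sum[idx3] + a3
    }
  }
  finalize_scores(struct, flex, S, count, a_sum, a_mean, a_sd)
}

#' Accumulate structure scores via the closed-form fast path
#'
#' Algebraic decomposition of the triplet sum, avoiding explicit C(N,3)
#' enumeration. For a candidate point with surrounding set R (|R| = N) and
#' member j:
#' sum over triplets containing j of (w_n + z_w\[j\]) =
#'   (4/3) C(N-1,2) z_w\[j\] + (N-2)/3 * sum of z_w over R minus j,
#' and the raw combination-score sum is (N-2) * P_j with
#' P_j = sum over other members m of p\[x_j, x_m\]. The second moment of the
#' per-membership combination scores, needed for the protein-wide
#' normalization, is (N-3) Q_j + P_j^2 per residue with
#' Q_j = sum of p\[x_j, x_m\]^2. Results agree with
#' [accumulate_scores_bruteforce()] to floating-point accuracy.
#'
#' @inheritParams accumulate_scores_bruteforce
#' @return A `catres_scores` data frame (see
#'   [accumulate_scores_bruteforce()]).
#' @export
accumulate_scores_fast <- function(struct, candidates, flex, profiles) {
  n <- nrow(struct$residues)
  ctx <- point_context(struct, candidates, flex, profiles)
  # pass 1: exact moments of the per-membership combination-score multiset
  tot_n <- 0; tot_a <- 0; tot_a2 <- 0
  for (cx in ctx) {
    N <- length(cx$idx)
    P <- rowSums(cx$M) - diag(cx$M)
    Q <- rowSums(cx$M^2) - diag(cx$M)^2
    cN12 <- choose(N - 1, 2)
    tot_n <- tot_n + N * cN12
    tot_a <- tot_a + (N - 2) * sum(P)
    tot_a2 <- tot_a2 + sum((N - 3) * Q + P^2)
  }
  a_mean <- if (tot_n > 0) tot_a / tot_n else 0
  a_var <- if (tot_n > 0) max(0, tot_a2 / tot_n - a_mean^2) else 0
  a_sd <- sqrt(a_var)
  # guard against cancellation noise when the multiset is constant
  if (a_sd < 1e-8 * (1 + abs(a_mean))) a_sd <- 0
  if (tot_n > 0 && a_sd == 0)
    warning("constant combination scores: all z_a set to 0")
  S <- numeric(n); count <- integer(n); a_sum <- numeric(n)
  for (cx in ctx) {
    idx <- cx$idx
    N <- length(idx)
    cN12 <- choose(N - 1, 2)
    zw <- cx$z_w
    Tw <- sum(zw)
    P <- rowSums(cx$M) - diag(cx$M)
    contrib_w <- (4 / 3) * cN12 * zw + (N - 2) / 3 * (Tw - zw)
    a_raw <- (N - 2) * P
    contrib_a <- if (a_sd > 0) (a_raw - cN12 * a_mean) / a_sd else 0
    S[idx] <- S[idx] + contrib_w + contrib_a
    count[idx] <- count[idx] + cN12
    a_sum[idx] <- a_sum[idx] + a_raw
  }
  finalize_scores(struct, flex, S, count, a_sum, a_mean, a_sd)
}

#' Rank residues by score
#'
#' Orders the score table descending by `S` (or by `S_prime` when present,
#' i.e. after conservation fusion). Residues that entered no triplet keep
#' S = 0 and are placed after all scored residues; ties and the unscored
#' block are broken by (chain, residue number, insertion code) ascending.
#' A 1-based `rank` column is assigned.
#'
#' @param scores a `catres_scores` data frame.
#' @return the same data frame, reordered, with a `rank` column.
#' @export
rank_residues <- function(scores) {
  key <- if ("S_prime" %in% names(scores) && !all(is.na(scores$S_prime)))
    scores$S_prime else scores$S
  scored <- scores$triplet_count > 0
  ord <- order(!scored, -ifelse(scored, key, 0),
               scores$chain, scores$resno, scores$icode)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Auxiliary report for backbone-functional residue types
#'
#' Roughly one in twenty catalytic residues acts through a backbone atom and
#' belongs to one of the 8 amino-acid types without a side-chain vector
#' (GLY, ALA, VAL, LEU, ILE, PRO, PHE, MET). These types cannot enter the
#' orientation ranking; as a courtesy this report lists, for every such
#' residue, its rigidity z-score and its best pairwise profile affinity
#' (max over partner types of p_x\[y\]). It is auxiliary output, not a
#' ranking.
#'
#' @param struct a `catres_structure`.
#' @param flex a `catres_flexibility` from [wcn()].
#' @param profiles a `catres_profiles` matrix.
#' @return data frame with columns `chain`, `resno`, `icode`, `aa`, `z_wcn`,
#'   `best_profile_affinity`.
#' @export
backbone_report <- function(struct, flex, profiles) {
  r <- struct$residues
  keep <- which(!r$aa %in% names(SIDECHAIN_VECTOR_ATOMS))
  data.frame(chain = r$chain[keep], resno = r$resno[keep],
             icode = r$icode[keep], aa = r$aa[keep],
             z_wcn = flex$z_w[keep],
             best_profile_affinity = if (length(keep))
               apply(unclass(profiles)[r$aa[keep], , drop = FALSE], 1, max)
             else numeric(0),
             stringsAsFactors = FALSE, row.names = NULL)
}
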