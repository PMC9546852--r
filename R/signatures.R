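#' Cosine similarity between two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length, not both zero.
#' @return Scale-invariant similarity in [0, 1] for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Pairwise cosine similarity between matrix columns
#'
#' @param A,B Matrices with the same number of rows.
#' @return `ncol(A)` x `ncol(B)` matrix of cosine similarities.
#' @export
cosine_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  t(An) %*% Bn
}

.kl_div <- function(V, WH, eps = 1e-12) {
  sum(ifelse(V > 0, V * log(V / (WH + eps)), 0) - V + WH)
}

.nmf_run <- function(V, rank, tol, max_iter, eps = 1e-12) {
  nc <- nrow(V); ns <- ncol(V)
  W <- matrix(stats::runif(nc * rank, 0.1, 1), nc, rank)
  H <- matrix(stats::runif(rank * ns, 0.1, 1), rank, ns)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    R <- V / (WH + eps)
    H <- H * (t(W) %*% R) / (colSums(W) + eps)
    WH <- W %*% H
    R <- V / (WH + eps)
    W <- W * (R %*% t(H)) / sweep(matrix(1, nc, rank), 2, rowSums(H) + eps, "*")
    if (it %% 10 == 0 || it == max_iter) {
      obj <- .kl_div(V, W %*% H, eps)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(1, abs(obj_prev))) {
        obj_prev <- obj
        break
      }
      obj_prev <- obj
    }
  }
  list(W = W, H = H, obj = .kl_div(V, W %*% H, eps), iter = it)
}

#' De novo mutational signature extraction by NMF
#'
#' Factorises the samples x channels count matrix into `rank` signatures
#' and per-sample contributions by multiplicative-update non-negative
#' matrix factorisation minimising the generalised Kullback-Leibler
#' divergence (the Poisson-flavoured objective appropriate for count
#' catalogs). The best of `n_restarts` random initialisations (by final
#' objective) is returned; signatures are column-normalised to probability
#' profiles with contributions rescaled so the reconstruction is unchanged.
#'
#' @param mat Samples x channels non-negative count matrix.
#' @param rank Number of signatures; must be < min(dim(mat)).
#' @param n_restarts Random restarts (default 100).
#' @param seed Optional seed; a fixed seed makes the result reproducible.
#' @param tol Relative convergence tolerance on the objective.
#' @param max_iter Maximum multiplicative updates per restart.
#' @return A list of class `nmf_result`: `rank`, `signatures` (channels x
#'   rank, columns sum to 1), `contributions` (samples x rank, mutation
#'   counts), `objective`, `n_restarts`, `seed`.
#' @export
extract_denovo <- function(mat, rank, n_restarts = 100, seed = NULL,
                           tol = 1e-6, max_iter = 2000) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(mat == 0)) stop("all-zero matrix cannot be factorised", call. = FALSE)
  if (rank >= min(dim(mat))) stop("rank must be < min(n_samples, n_channels)", call. = FALSE)
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  V <- t(mat)  # channels x samples
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- .nmf_run(V, rank, tol, max_iter)
    if (is.null(best) || res$obj < best$obj) best <- res
  }
  scale <- colSums(best$W)
  sig <- sweep(best$W, 2, scale, "/")
  contrib <- t(best$H * scale)  # samples x rank
  ord <- order(colSums(contrib), decreasing = TRUE)
  sig <- sig[, ord, drop = FALSE]
  contrib <- contrib[, ord, drop = FALSE]
  colnames(sig) <- colnames(contrib) <- paste0("denovo", seq_len(rank))
  rownames(sig) <- colnames(mat)
  rownames(contrib) <- rownames(mat)
  structure(list(rank = rank, signatures = sig, contributions = contrib,
                 objective = best$obj, n_restarts = n_restarts, seed = seed),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("NMF: rank %d, %d restarts, KL objective %.3f\n",
              x$rank, x$n_restarts, x$objective))
  invisible(x)
}

#' Select the NMF rank by matching de novo signatures to a reference
#'
#' Extracts de novo signatures at each candidate rank and greedily matches
#' de novo signatures to reference signatures one-to-one, in decreasing
#' order of cosine similarity (each reference claimable once, so an
#' overfit rank splitting one process into near-duplicates cannot match
#' the same reference twice). The chosen rank is the largest at which
#' every de novo signature attains a cosine of
#' at least `min_cosine` to its matched reference; signatures below threshold at
#' other ranks are flagged as novel and reported together with the best
#' non-negative mixture of reference signatures approximating them (a
#' treatment process can resemble a mix of reference profiles).
#'
#' @param mat Samples x channels count matrix.
#' @param reference Channels x signatures reference profile matrix.
#' @param ranks Candidate ranks (e.g. `1:4`).
#' @param min_cosine Match threshold (default 0.8).
#' @param n_restarts Restarts per extraction (default 30).
#' @param seed Optional seed.
#' @return A list: `rank` (chosen), `report` (data.frame with per-rank,
#'   per-signature best match, cosine, matched flag, mixture cosine and
#'   mixture components), `results` (the `nmf_result` per rank).
#' @export
select_rank <- function(mat, reference, ranks, min_cosine = 0.8,
                        n_restarts = 30, seed = NULL) {
  stopifnot(length(ranks) >= 1)
  ranks <- sort(unique(as.integer(ranks)))
  if (!is.null(seed)) set.seed(seed)
  reference <- as.matrix(reference)
  report <- list(); results <- list(); ok <- logical(length(ranks))
  for (i in seq_along(ranks)) {
    k <- ranks[i]
    ext <- extract_denovo(mat, k, n_restarts = n_restarts)
    results[[as.character(k)]] <- ext
    cm <- cosine_matrix(ext$signatures, reference)
    # one-to-one greedy matching: each reference signature can be claimed
    # by at most one de novo signature, in decreasing order of cosine, so
    # an overfit rank that splits one process into near-duplicates cannot
    # count the same reference twice
    best_j <- rep(NA_integer_, k)
    avail <- rep(TRUE, ncol(cm))
    pairs <- order(cm, decreasing = TRUE)
    for (p in pairs) {
      s <- (p - 1) %% k + 1
      r <- (p - 1) %/% k + 1
      if (is.na(best_j[s]) && avail[r]) {
        best_j[s] <- r
        avail[r] <- FALSE
      }
    }
    best_cos <- cm[cbind(seq_len(k), best_j)]
    best_cos[is.na(best_cos)] <- 0  # rank exceeded the reference set
    mix_cos <- rep(NA_real_, k); mix_top <- rep(NA_character_, k)
    for (s in which(best_cos < min_cosine)) {
      x <- pracma::lsqnonneg(reference, ext$signatures[, s])$x
      rec <- as.vector(reference %*% x)
      if (sum(rec) > 0) {
        mix_cos[s] <- cosine_similarity(ext$signatures[, s], rec)
        top <- order(x, decreasing = TRUE)[seq_len(min(2, sum(x > 0)))]
        mix_top[s] <- paste(colnames(reference)[top], collapse = "+")
      }
    }
    report[[i]] <- data.frame(
      rank = k, signature = colnames(ext$signatures),
      best_reference = colnames(reference)[best_j], cosine = best_cos,
      matched = best_cos >= min_cosine, novel = best_cos < min_cosine,
      mixture_cosine = mix_cos, mixture = mix_top, stringsAsFactors = FALSE)
    ok[i] <- all(best_cos >= min_cosine)
  }
  chosen <- if (any(ok)) max(ranks[ok]) else min(ranks)
  list(rank = chosen, report = do.call(rbind, report), results = results)
}

#' Merge reference signatures into a single profile
#'
#' Replaces the grouped columns by their renormalised sum (so exposures on
#' the merged signature count mutations from either component), leaving all
#' other columns untouched. Used e.g. to merge SBS17a and SBS17b into one
#' 5-FU signature.
#'
#' @param reference Channels x signatures profile matrix.
#' @param group Character vector of column names to merge.
#' @param new_name Name of the merged column.
#' @return The modified profile matrix (merged column at the position of
#'   the first group member).
#' @export
merge_signatures <- function(reference, group, new_name) {
  reference <- as.matrix(reference)
  missing <- setdiff(group, colnames(reference))
  if (length(missing)) stop("unknown signature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  merged <- rowSums(reference[, group, drop = FALSE])
  merged <- merged / sum(merged)
  nms <- colnames(reference)
  pos <- min(match(group, nms))
  keep_idx <- which(!nms %in% group)
  left <- keep_idx[keep_idx < pos]
  right <- keep_idx[keep_idx > pos]
  out <- cbind(reference[, left, drop = FALSE], merged,
               reference[, right, drop = FALSE])
  colnames(out) <- c(nms[left], new_name, nms[right])
  out
}

.nnls_exposures <- function(sig, catalog) {
  fit <- pracma::lsqnonneg(sig, catalog)
  fit$x
}

#' Strict constrained signature refitting
#'
#' Step 1: non-negative least squares of the sample catalog on the allowed
#' signature profiles. Step 2 (backwards elimination against overfitting):
#' repeatedly try removing each remaining signature, refit, and remove the
#' one whose removal decreases the reconstruction cosine the least, as long
#' as that decrease is below `max_delta`. Step 3: final NNLS exposures on
#' the surviving signatures; removed signatures get exposure 0.
#'
#' @param catalog Non-negative channel count vector for one sample.
#' @param signatures Channels x signatures profile matrix (columns sum to 1).
#' @param max_delta Maximum tolerated decrease in reconstruction cosine per
#'   removal (default 0.004).
#' @return A list of class `exposure_fit`: `exposures` (named, counts),
#'   `reconstructed_cosine`, `removed` (character), `all_zero` flag.
#' @export
refit_strict <- function(catalog, signatures, max_delta = 0.004) {
  sig <- as.matrix(signatures)
  catalog <- as.numeric(catalog)
  stopifnot(length(catalog) == nrow(sig))
  if (any(catalog < 0)) stop("catalog must be non-negative", call. = FALSE)
  nms <- colnames(sig) %||% paste0("sig", seq_len(ncol(sig)))
  colnames(sig) <- nms
  if (sum(catalog) == 0) {
    return(structure(list(exposures = stats::setNames(numeric(length(nms)), nms),
                          reconstructed_cosine = NA_real_, removed = character(0),
                          all_zero = TRUE), class = "exposure_fit"))
  }
  cos_of <- function(keep) {
    x <- .nnls_exposures(sig[, keep, drop = FALSE], catalog)
    rec <- as.vector(sig[, keep, drop = FALSE] %*% x)
    c(cos = if (sum(rec) == 0) 0 else cosine_similarity(catalog, rec))
  }
  keep <- nms
  current <- cos_of(keep)
  removed <- character(0)
  while (length(keep) > 1) {
    trial <- vapply(keep, function(s) cos_of(setdiff(keep, s)), numeric(1))
    s_best <- names(which.max(trial))
    if (current - trial[[s_best]] < max_delta) {
      keep <- setdiff(keep, s_best)
      removed <- c(removed, s_best)
      current <- trial[[s_best]]
    } else break
  }
  x <- .nnls_exposures(sig[, keep, drop = FALSE], catalog)
  exposures <- stats::setNames(numeric(length(nms)), nms)
  exposures[keep] <- x
  structure(list(exposures = exposures, reconstructed_cosine = unname(current),
                 removed = removed, all_zero = FALSE), class = "exposure_fit")
}

#' Strict refit of every sample in a context matrix
#'
#' @param mat Samples x channels count matrix.
#' @param signatures Channels x signatures profile matrix.
#' @param max_delta Per-removal cosine tolerance (see [refit_strict()]).
#' @return A list: `exposures` (samples x signatures count matrix),
#'   `cosine` (per-sample reconstruction cosine, NA for empty catalogs).
#' @export
fit_exposures <- function(mat, signatures, max_delta = 0.004) {
  mat <- as.matrix(mat)
  fits <- lapply(seq_len(nrow(mat)), function(i) refit_strict(mat[i, ], signatures, max_delta))
  exposures <- do.call(rbind, lapply(fits, `[[`, "exposures"))
  rownames(exposures) <- rownames(mat)
  cosine <- vapply(fits, `[[`, numeric(1), "reconstructed_cosine")
  names(cosine) <- rownames(mat)
  list(exposures = exposures, cosine = cosine)
}

#' Relative signature contributions
#'
#' Exposure divided by the sample's total burden of that mutation type.
#'
#' @param exposures Samples x signatures count matrix.
#' @param burdens Per-sample total burdens (same order); defaults to the
#'   exposure row sums.
#' @return Matrix of fractions.
#' @export
relative_contribution <- function(exposures, burdens = rowSums(exposures)) {
  sweep(exposures, 1, pmax(burdens, 1e-12), "/")
}

.SIG_SETS <- list(
  colon = list(
    SBS96 = list(aging = c("SBS1", "SBS5", "SBS18"), other = "SBS88",
                 treatment = c("SBS17", "SBS35")),
    DBS78 = list(aging = c("DBS2", "DBS4", "DBS6", "DBS9", "DBS11"), other = character(0),
                 treatment = "DBS5"),
    ID83 = list(aging = c("ID1", "ID2", "ID5"), other = "ID18",
                treatment = "ID8")
  ),
  liver = list(
    SBS96 = list(aging = c("SBS1", "SBS5", "SBS18"), other = character(0),
                 treatment = c("SBS17", "SBS35")),
    DBS78 = list(aging = c("DBS2", "DBS4", "DBS6", "DBS9", "DBS11"), other = character(0),
                 treatment = "DBS5"),
    ID83 = list(aging = c("ID1", "ID2", "ID5"), other = character(0),
                treatment = "ID8")
  )
)

#' Constrained signature set for strict refitting
#'
#' Returns the tissue-specific signature set used for constrained
#' refitting: the established aging signatures plus treatment signatures
#' (5-FU SBS17 merged, platinum SBS35/DBS5, radiation ID8). Non-treatment
#' signatures are kept only if their matched de novo relative contribution
#' reaches `threshold` (10%) in at least one sample, when de novo
#' contributions are supplied; treatment signatures are always retained for
#' treated cohorts.
#'
#' @param tissue `"colon"` or `"liver"`.
#' @param mut_type `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @param denovo_contrib Optional named numeric vector (max relative de
#'   novo contribution per reference signature, fractions) or samples x
#'   signatures matrix of relative contributions.
#' @param threshold Inclusion threshold (default 0.10).
#' @param treated Whether the cohort contains treated donors (retains the
#'   treatment signatures).
#' @return Character vector of signature names.
#' @export
signature_set <- function(tissue = c("colon", "liver"),
                          mut_type = c("SBS96", "DBS78", "ID83"),
                          denovo_contrib = NULL, threshold = 0.10,
                          treated = TRUE) {
  tissue <- match.arg(tissue)
  mut_type <- match.arg(mut_type)
  sets <- .SIG_SETS[[tissue]][[mut_type]]
  optional <- c(sets$aging, sets$other)
  if (!is.null(denovo_contrib)) {
    if (is.matrix(denovo_contrib)) {
      denovo_contrib <- apply(denovo_contrib, 2, max)
    }
    known <- names(denovo_contrib)
    keep <- vapply(optional, function(s) {
      !(s %in% known) || denovo_contrib[[s]] >= threshold
    }, logical(1))
    optional <- optional[keep]
  }
  out <- c(optional, if (treated) sets$treatment)
  unname(out)
}

.block_profile <- function(n_channels, idx, weight = 0.92) {
  p <- rep((1 - weight) / n_channels, n_channels)
  w <- seq(2, 1, length.out = length(idx))
  p[idx] <- p[idx] + weight * w / sum(w)
  p / sum(p)
}

#' Synthetic reference signature set
#'
#' A deterministic, near-orthogonal set of reference profiles named after
#' the processes they stand in for (aging SBS1/SBS5/SBS18, 5-FU
#' SBS17a/SBS17b, platinum SBS35/DBS5, colibactin SBS88/ID18, radiation
#' ID8, ...). These are synthetic constructions for simulation and testing
#' --- each concentrates its mass on a biologically motivated channel block
#' (e.g. SBS1 on N[C>T]G, ID8 on >=5 bp deletions without microhomology)
#' --- and are **not** estimates of the COSMIC catalogue profiles.
#'
#' @param mut_type `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @return Channels x signatures matrix; columns sum to 1.
#' @export
synthetic_reference_signatures <- function(mut_type = c("SBS96", "DBS78", "ID83")) {
  mut_type <- match.arg(mut_type)
  if (mut_type == "SBS96") {
    ch <- sbs96_channels()
    blocks <- list(
      SBS1 = grep("\\[C>T\\]G$", ch),             # CpG deamination
      SBS5 = seq_along(ch),                        # flat clock-like
      SBS18 = grep("^[AC]\\[C>A\\]", ch),          # oxidative damage
      SBS17a = grep("\\[T>C\\]", ch),              # 5-FU component a
      SBS17b = grep("[AC]\\[T>G\\]", ch),          # 5-FU component b
      SBS35 = c(grep("^[GT]\\[C>A\\]", ch), grep("G\\[T>A\\]", ch)),  # platinum
      SBS88 = grep("\\[C>G\\]", ch)                # colibactin
    )
    weights <- c(SBS1 = 0.95, SBS5 = 1.0, SBS18 = 0.92, SBS17a = 0.93,
                 SBS17b = 0.93, SBS35 = 0.92, SBS88 = 0.92)
  } else if (mut_type == "DBS78") {
    ch <- dbs78_channels()
    blocks <- list(
      DBS2 = grep("^CC>T", ch),
      DBS4 = grep("^GC>A", ch),
      DBS6 = grep("^TA>", ch),
      DBS9 = grep("^TC>", ch),
      DBS11 = grep("^GC>[CT]", ch),
      DBS5 = match(c("CT>AA", "CT>AC"), ch)        # platinum doublets
    )
    weights <- c(DBS2 = 0.9, DBS4 = 0.9, DBS6 = 0.9, DBS9 = 0.9,
                 DBS11 = 0.9, DBS5 = 0.95)
  } else {
    ch <- id83_channels()
    blocks <- list(
      ID1 = grep("^INS\\.T\\.1\\.[45]", ch),        # T insertions at long runs
      ID2 = grep("^DEL\\.T\\.1\\.[56]", ch),        # T deletions at long runs
      ID5 = grep("^DEL\\.T\\.1\\.[123]", ch),
      ID8 = grep("^DEL\\.rep\\.5\\+\\.[01]$", ch),  # >=5 bp deletions, no microhomology
      ID18 = grep("^INS\\.rep\\.[23]", ch)
    )
    weights <- c(ID1 = 0.93, ID2 = 0.93, ID5 = 0.93, ID8 = 0.95, ID18 = 0.92)
  }
  sig <- vapply(names(blocks), function(s) {
    if (s == "SBS5") rep(1 / length(ch), length(ch))
    else .block_profile(length(ch), blocks[[s]], weights[[s]])
  }, numeric(length(ch)))
  rownames(sig) <- ch
  sig
}
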