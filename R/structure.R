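#' Mean-impute and center a genotype matrix
#'
#' Missing dosages are replaced by the per-variant mean over observed
#' calls, then each column is mean-centered. No variance scaling is
#' applied (centering only is the DAPC convention for biallelic
#' dosages; scaling is available via `scale = TRUE`).
#'
#' @param dataset A `genotype_dataset` (QC'd; for structure analyses
#'   also LD-pruned).
#' @param scale Divide columns by their standard deviation as well.
#' @return A list with `X` (numeric samples x variants matrix) and
#'   `variant_means` (named numeric, the imputation/centering means on
#'   the dosage scale).
#' @export
center_matrix <- function(dataset, scale = FALSE) {
  X <- dataset$calls
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu))) {
    stop("all-missing variant encountered; run apply_qc() first")
  }
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) X[na_idx] <- mu[na_idx[, 2]]
  X <- sweep(X, 2, mu, "-")
  if (scale) {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(X, 2, sdv, "/")
  }
  list(X = X, variant_means = stats::setNames(mu, colnames(X)))
}

#' Principal component analysis of a centered genotype matrix
#'
#' Thin SVD-based PCA. Eigenvalues are the component variances
#' (squared singular values over `n - 1`); the cumulative fraction of
#' total variance is available from [generics::tidy()].
#'
#' @param centered A list from [center_matrix()] (or a bare centered
#'   matrix).
#' @param n_components Number of components to retain.
#' @return An object of class `pca_basis`: `loadings` (variants x
#'   components, orthonormal columns), `eigenvalues`, `scores`
#'   (samples x components), `total_variance`, `variant_means`,
#'   `variant_ids`.
#' @export
pca <- function(centered, n_components) {
  if (is.matrix(centered)) centered <- list(X = centered,
                                            variant_means = NULL)
  X <- centered$X
  n <- nrow(X)
  if (n_components > min(dim(X))) {
    stop("n_components (", n_components, ") exceeds min(dim) = ",
         min(dim(X)))
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  eig <- sv$d^2 / (n - 1)
  structure(list(
    loadings = sv$v,
    eigenvalues = eig[seq_len(n_components)],
    scores = sv$u %*% diag(sv$d[seq_len(n_components)],
                           nrow = n_components),
    total_variance = sum(X^2) / (n - 1),
    variant_means = centered$variant_means,
    variant_ids = colnames(X),
    n_components = n_components
  ), class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components, %.1f%% of total variance\n",
              x$n_components,
              100 * sum(x$eigenvalues) / x$total_variance))
  invisible(x)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' K-means cluster-number scan with BIC
#'
#' For each K in `1..k_max`, the best of `n_starts` Lloyd K-means
#' solutions (random data-point initializations) is kept, plus one
#' deterministic warm start that augments the previous K's best
#' centers with the worst-fitted point — which guarantees the
#' within-cluster sum of squares is non-increasing in K. The
#' cluster-number score is the spherical-Gaussian profile BIC
#' `BIC(K) = n log(WSS_K / n) + K log(n)`; `delta_bic` holds the
#' consecutive improvements `BIC(K) - BIC(K+1)`, with values above 2
#' read as strong evidence for K+1 over K.
#'
#' @param scores Samples x components matrix (typically PCA scores).
#' @param k_max Largest cluster number scanned (default 20).
#' @param n_starts Random initializations per K (default 10).
#' @param seed Integer seed for the initialization stream.
#' @return An object of class `bic_scan`: tibble `scan` (`k`, `wss`,
#'   `bic`, `delta_bic`), `k_best`, `cluster` (assignment at
#'   `k_best`), `n`.
#' @export
kmeans_bic_scan <- function(scores, k_max = 20, n_starts = 10,
                            seed = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(n > k_max, ncol(scores) >= 1)
  with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    wss <- numeric(k_max)
    assign_list <- vector("list", k_max)
    prev_centers <- NULL
    for (K in seq_len(k_max)) {
      if (K == 1) {
        ctr <- matrix(colMeans(scores), nrow = 1)
        wss[1] <- sum(sweep(scores, 2, ctr[1, ], "-")^2)
        assign_list[[1]] <- rep(1L, n)
        prev_centers <- ctr
        next
      }
      best <- NULL
      run_km <- function(centers0) {
        tryCatch(
          suppressWarnings(stats::kmeans(scores, centers = centers0,
                                         iter.max = 300,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
      }
      for (s in seq_len(n_starts)) {
        km <- NULL
        tries <- 0
        while (is.null(km) && tries < 20) {
          centers0 <- scores[sample.int(n, K), , drop = FALSE]
          km <- run_km(centers0)
          tries <- tries + 1
        }
        if (!is.null(km) &&
            (is.null(best) || km$tot.withinss < best$tot.withinss)) {
          best <- km
        }
      }
      # warm start: previous centers + the point farthest from its center
      d2 <- rowSums((scores - prev_centers[
        apply_centers(scores, prev_centers), , drop = FALSE])^2)
      warm0 <- rbind(prev_centers, scores[which.max(d2), ])
      km <- run_km(warm0)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
      if (is.null(best)) stop("K-means failed for K = ", K)
      wss[K] <- best$tot.withinss
      assign_list[[K]] <- best$cluster
      prev_centers <- best$centers
    }
    bic <- n * log(wss / n) + seq_len(k_max) * log(n)
    k_best <- which.min(bic)
    scan <- tibble::tibble(
      k = seq_len(k_max), wss = wss, bic = bic,
      delta_bic = c(bic[-k_max] - bic[-1], NA_real_)
    )
    structure(list(scan = scan, k_best = k_best,
                   cluster = assign_list[[k_best]], n = n),
              class = "bic_scan")
  })
}

apply_centers <- function(X, centers) {
  d <- outer(rowSums(X^2), rowSums(centers^2), "+") -
    2 * X %*% t(centers)
  max.col(-d, ties.method = "first")
}

#' @export
print.bic_scan <- function(x, ...) {
  cat(sprintf("<bic_scan> K = 1..%d over %d samples; k_best = %d\n",
              nrow(x$scan), x$n, x$k_best))
  invisible(x)
}

#' Fit a discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant axes maximizing the between- over within-group
#' variance ratio in the retained-PC subspace, via the generalized
#' eigenproblem solved on the Cholesky-whitened between-group matrix.
#' Axes are scaled so the pooled within-group covariance is the
#' identity in discriminant space, which makes the assignment
#' posterior a plain Gaussian on discriminant distances. A singular
#' pooled covariance is ridge-regularized
#' (`eps = 1e-8 * trace / n_pcs`) with a warning. Group priors are
#' proportional to training group sizes.
#'
#' @param scores Samples x components matrix (PCA scores), or a
#'   `pca_basis` whose scores should be used.
#' @param labels Group label per sample.
#' @param n_pcs Number of leading components to retain.
#' @param n_da Number of discriminant axes
#'   (default `min(n_pcs, n_groups - 1)`).
#' @param basis Optional `pca_basis` carried along so
#'   [dapc_predict()] can project raw genotypes.
#' @return An object of class `dapc`.
#' @export
dapc_fit <- function(scores, labels, n_pcs = NULL, n_da = NULL,
                     basis = NULL) {
  if (inherits(scores, "pca_basis")) {
    basis <- scores
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("every group needs >= 2 members")
  n_pcs <- n_pcs %||% ncol(scores)
  stopifnot(n_pcs >= 1, n_pcs <= ncol(scores))
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  G <- nlevels(labels)
  n <- nrow(X)
  n_da <- n_da %||% min(n_pcs, G - 1)
  n_da <- min(n_da, n_pcs, G - 1)

  ng <- as.numeric(table(labels))
  M <- do.call(rbind, lapply(levels(labels), function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  xbar <- colMeans(X)
  Xw <- X - M[as.integer(labels), , drop = FALSE]
  W <- crossprod(Xw) / (n - G)
  Mc <- sweep(M, 2, xbar, "-")
  B <- crossprod(Mc * sqrt(ng)) / max(1, G - 1)

  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular pooled within-group covariance; ridge applied")
    eps <- 1e-8 * sum(diag(W)) / n_pcs
    R <- chol(W + diag(eps, n_pcs))
  }
  Rinv <- backsolve(R, diag(n_pcs))
  S <- t(Rinv) %*% B %*% Rinv
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  axes <- Rinv %*% es$vectors[, seq_len(n_da), drop = FALSE]

  structure(list(
    axes = axes,
    eigenvalues = pmax(es$values[seq_len(n_da)], 0),
    group_labels = levels(labels),
    group_means_pc = M,
    group_means_da = M %*% axes,
    priors = ng / n,
    n_pcs = n_pcs, n_da = n_da,
    labels = labels,
    scores_pc = X,
    scores_da = X %*% axes,
    basis = basis
  ), class = "dapc")
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf(
    "<dapc> %d groups, %d retained PCs, %d discriminant axes\n",
    length(x$group_labels), x$n_pcs, x$n_da
  ))
  invisible(x)
}

#' Assign samples to groups with a fitted DAPC
#'
#' New samples are projected into the model's discriminant space; raw
#' genotypes are imputed and centered with the model's own variant
#' means (never the new data's) before projection. Posterior
#' membership probabilities are Gaussian on discriminant-space
#' distances (identity within-group covariance by construction), times
#' the training priors, row-normalized.
#'
#' @param model A fitted [dapc_fit()] object.
#' @param newdata A `genotype_dataset` (requires the model to carry a
#'   `pca_basis`) or a samples x components score matrix compatible
#'   with the model's PC space.
#' @return An object of class `dapc_assignment`: `posterior` (samples
#'   x groups, rows sum to 1), `assigned` (label per sample).
#' @export
dapc_predict <- function(model, newdata) {
  if (inherits(newdata, "genotype_dataset")) {
    if (is.null(model$basis)) {
      stop("model carries no PCA basis; supply scores instead")
    }
    ids <- model$basis$variant_ids
    missing_v <- setdiff(ids, newdata$variants$variant_id)
    if (length(missing_v)) {
      stop("new data lacks model variants: ",
           paste(utils::head(missing_v, 5), collapse = ", "),
           if (length(missing_v) > 5) " ...")
    }
    X <- newdata$calls[, ids, drop = FALSE]
    storage.mode(X) <- "double"
    mu <- model$basis$variant_means
    na_idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(na_idx)) X[na_idx] <- mu[na_idx[, 2]]
    X <- sweep(X, 2, mu, "-")
    scores <- X %*% model$basis$loadings
  } else {
    scores <- as.matrix(newdata)
  }
  da <- scores[, seq_len(model$n_pcs), drop = FALSE] %*% model$axes
  d2 <- outer(rowSums(da^2), rowSums(model$group_means_da^2), "+") -
    2 * da %*% t(model$group_means_da)
  logp <- sweep(-0.5 * d2, 2, log(model$priors), "+")
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  colnames(post) <- model$group_labels
  rownames(post) <- rownames(scores)
  assigned <- factor(model$group_labels[max.col(post, ties.method = "first")],
                     levels = model$group_labels)
  structure(list(posterior = post, assigned = assigned),
            class = "dapc_assignment")
}

#' Reassignment accuracy of a DAPC model
#'
#' @param assignment A `dapc_assignment` (or a vector of assigned
#'   labels).
#' @param labels The prior (true) label per sample.
#' @return A list with `overall` (fraction correct) and `by_group`
#'   (tibble `group`, `n`, `accuracy`).
#' @export
reassignment_accuracy <- function(assignment, labels) {
  assigned <- if (inherits(assignment, "dapc_assignment")) {
    as.character(assignment$assigned)
  } else {
    as.character(assignment)
  }
  labels <- as.character(labels)
  stopifnot(length(assigned) == length(labels))
  ok <- assigned == labels
  by_group <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = labels, ok = ok), .data$group),
    n = dplyr::n(), accuracy = mean(.data$ok), .groups = "drop"
  )
  list(overall = mean(ok), by_group = by_group)
}

stratified_split <- function(labels, fraction, max_tries = 100) {
  labels <- factor(labels)
  for (t in seq_len(max_tries)) {
    train <- unlist(lapply(levels(labels), function(g) {
      idx <- which(labels == g)
      n_tr <- max(1L, round(fraction * length(idx)))
      n_tr <- min(n_tr, length(idx) - 1L)  # keep >= 1 in hold-out
      sample(idx, n_tr)
    }))
    if (all(levels(labels) %in% labels[train]) &&
        all(levels(labels) %in% labels[-train])) {
      return(sort(train))
    }
  }
  stop("could not produce a stratified split with all groups present")
}

#' Cross-validated choice of the number of retained PCs
#'
#' Repeated stratified hold-out: per replicate the data are split
#' `training_fraction` : rest within each group, a DAPC is fitted on
#' the training scores at each candidate PC count, and hold-out
#' assignment success is recorded. `RMSE(n_pcs) =
#' sqrt(mean((1 - success)^2))` over replicates; the chosen count
#' minimizes RMSE (ties go to the smaller count).
#'
#' @param scores Samples x components matrix (full-data PCA scores).
#' @param labels Group label per sample.
#' @param npc_grid Candidate PC counts (each <= `ncol(scores)`).
#' @param training_fraction Training share per group (default 0.9).
#' @param reps Replicates (default 30).
#' @param seed Integer seed.
#' @return An object of class `dapc_xval`: `results` tibble
#'   (`n_pcs`, `rep`, `success`), `rmse` tibble (`n_pcs`, `rmse`),
#'   `chosen_npcs`.
#' @export
xval_select_npcs <- function(scores, labels, npc_grid,
                             training_fraction = 0.9, reps = 30,
                             seed = NULL) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  npc_grid <- sort(unique(as.integer(npc_grid)))
  stopifnot(all(npc_grid >= 1), all(npc_grid <= ncol(scores)))
  with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    res <- vector("list", reps)
    for (r in seq_len(reps)) {
      tr <- stratified_split(labels, training_fraction)
      succ <- vapply(npc_grid, function(p) {
        fit <- dapc_fit(scores[tr, , drop = FALSE], labels[tr],
                        n_pcs = p)
        pred <- dapc_predict(fit, scores[-tr, , drop = FALSE])
        mean(as.character(pred$assigned) ==
               as.character(labels[-tr]))
      }, numeric(1))
      res[[r]] <- tibble::tibble(n_pcs = npc_grid, rep = r,
                                 success = succ)
    }
    results <- dplyr::bind_rows(res)
    rmse <- dplyr::summarise(
      dplyr::group_by(results, .data$n_pcs),
      rmse = sqrt(mean((1 - .data$success)^2)), .groups = "drop"
    )
    chosen <- rmse$n_pcs[which.min(rmse$rmse)]
    structure(list(results = results, rmse = rmse,
                   chosen_npcs = chosen),
              class = "dapc_xval")
  })
}

#' Pairwise external validation of subgroup assignment
#'
#' For one pair of subgroups: repeated stratified 80:20 splits; per
#' repetition a PCA is fitted on the training genotypes, a two-group
#' DAPC (one discriminant axis) is trained, and the hold-out samples
#' are projected with the training means and loadings and assigned.
#' Accuracies are averaged over repetitions.
#'
#' @param dataset A `genotype_dataset` (QC'd and LD-pruned).
#' @param pair Character vector of two subgroup labels.
#' @param subgroups Named vector mapping sample_id to subgroup
#'   (default: the dataset's `subgroup` column).
#' @param training_fraction Training share per group (default 0.8).
#' @param reps Repetitions (default 10).
#' @param n_pcs PCs to retain (capped at the training rank, with a
#'   warning).
#' @param seed Integer seed.
#' @return An object of class `pairwise_validation`: `pair`,
#'   `per_rep_accuracy`, `mean`, `sd`.
#' @export
pairwise_external_validation <- function(dataset, pair, subgroups = NULL,
                                         training_fraction = 0.8,
                                         reps = 10, n_pcs = 50,
                                         seed = NULL) {
  stopifnot(length(pair) == 2)
  sg <- subgroups %||% stats::setNames(dataset$samples$subgroup,
                                       dataset$samples$sample_id)
  members <- names(sg)[sg %in% pair]
  if (min(table(factor(sg[members], levels = pair))) < 5) {
    stop("both subgroups need >= 5 members")
  }
  ds <- subset_dataset(dataset, samples = members)
  labels <- factor(sg[ds$samples$sample_id], levels = pair)
  with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- stratified_split(labels, training_fraction)
      train_ds <- subset_dataset(ds, samples = tr)
      val_ds <- subset_dataset(ds, samples = setdiff(seq_along(labels), tr))
      ctr <- center_matrix(train_ds)
      p_use <- min(n_pcs, nrow(ctr$X) - 1L, ncol(ctr$X))
      if (p_use < n_pcs) {
        warning("n_pcs capped at training rank (", p_use, ")")
      }
      basis <- pca(ctr, p_use)
      fit <- dapc_fit(basis, labels[tr], n_pcs = p_use, n_da = 1)
      pred <- dapc_predict(fit, val_ds)
      acc[r] <- mean(as.character(pred$assigned) ==
                       as.character(labels[-tr]))
    }
    structure(list(pair = pair, per_rep_accuracy = acc,
                   mean = mean(acc), sd = stats::sd(acc)),
              class = "pairwise_validation")
  })
}

#' @export
print.pairwise_validation <- function(x, ...) {
  cat(sprintf("<pairwise_validation> %s vs %s: mean %.3f (sd %.3f, %d reps)\n",
              x$pair[1], x$pair[2], x$mean, x$sd,
              length(x$per_rep_accuracy)))
  invisible(x)
}
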