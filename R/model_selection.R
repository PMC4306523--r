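# Random-effects Bayesian model selection: variational Dirichlet posterior
# over model frequencies, Monte-Carlo exceedance probabilities, family-level
# inference with the prior mass equalized across families, and the two-stage
# winning-model rule (best family first, then the best model within it).

#' Random-effects BMS: Dirichlet posterior over model frequencies
#'
#' Fixed-point variational scheme: each subject's posterior model
#' probabilities are proportional to `exp(log evidence + digamma(alpha_k) -
#' digamma(sum alpha))`; the concentration parameters accumulate the
#' expected assignments, iterated until the concentration vector changes by
#' less than `tol`.
#'
#' @param E Subjects x models matrix of approximate log evidences.
#' @param prior_alpha Prior concentration: a positive scalar (flat
#'   Dirichlet, default 1) or a full vector (used by family-level
#'   inference to equalize prior mass across families).
#' @param max_iter,tol Iteration cap and convergence tolerance on alpha.
#' @return A `dirichlet_posterior`: `alpha`, `expected_freq`
#'   (`alpha/sum(alpha)`), `assignments` (subjects x models), `prior_alpha`,
#'   `iterations`.
#' @export
rfx_bms <- function(E, prior_alpha = 1, max_iter = 2000, tol = 1e-6) {
  E <- as.matrix(E)
  K <- ncol(E)
  if (K < 2) stop("need at least 2 models")
  if (any(!is.finite(E))) stop("log evidences must be finite")
  alpha0 <- if (length(prior_alpha) == 1) rep(prior_alpha, K)
            else as.numeric(prior_alpha)
  if (length(alpha0) != K || any(alpha0 <= 0))
    stop("prior_alpha must be positive and match the model count")
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    lw <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      structure_out <- structure(
        list(alpha = setNames(alpha, colnames(E)),
             expected_freq = setNames(alpha / sum(alpha), colnames(E)),
             assignments = u, prior_alpha = alpha0, iterations = it),
        class = "dirichlet_posterior")
      return(structure_out)
    }
    change <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
  }
  stop("RFX-BMS did not converge after ", max_iter,
       " iterations (last max change ", signif(change, 3), ")")
}

#' Monte-Carlo exceedance probabilities of a Dirichlet posterior
#'
#' Estimates, for each component, the probability that its frequency
#' exceeds every other component's, from seeded Dirichlet draws (sampled in
#' memory-bounded chunks).
#'
#' @param post A `dirichlet_posterior`, or a bare concentration vector.
#' @param n_samples Number of Monte-Carlo draws (default 1e6).
#' @param seed Integer seed (recorded in the result).
#' @return Named numeric vector of exceedance probabilities (sums to 1 up
#'   to Monte-Carlo tie handling); attributes `n_samples` and `seed`.
#' @export
exceedance_probabilities <- function(post, n_samples = 1e6, seed = 1) {
  alpha <- if (inherits(post, "dirichlet_posterior")) post$alpha else post
  K <- length(alpha)
  counts <- with_seed(seed, {
    cnt <- integer(K)
    left <- n_samples
    while (left > 0) {
      m <- min(left, 1e5)
      G <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      win <- max.col(G, ties.method = "first")
      cnt <- cnt + tabulate(win, K)
      left <- left - m
    }
    cnt
  })
  structure(setNames(counts / n_samples, names(alpha)),
            n_samples = n_samples, seed = seed)
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Family-level random-effects BMS
#'
#' Each family is treated as one hypothesis with equal prior mass, its
#' prior spread uniformly over its member models (every model's prior mass
#' is its family's divided by the family size). A subject's family log
#' evidence is therefore the log-mean of its members' evidences
#' (`logsumexp(lnE) - log(size)`), and the random-effects Dirichlet update
#' runs over the four families with a flat prior -- which keeps the
#' variational digamma terms well-behaved for families of very different
#' sizes. Model-level expected frequencies and exceedance probabilities
#' come from a flat model-level RFX pass and are reported alongside.
#'
#' @param E Subjects x models log-evidence matrix (columns named by model
#'   id, aligned with the partition).
#' @param partition List of `model_family` objects covering all columns.
#' @param prior_alpha Prior concentration per family (default 1, flat).
#' @param n_samples,seed Monte-Carlo settings for the exceedance
#'   probabilities.
#' @return A `bms_result`: model-level `alpha`, `expected_freq`,
#'   `exceedance`; `family` (data.frame: family, size, alpha,
#'   expected_freq, exceedance); `fam_of` (family index per model column);
#'   `n_samples`, `seed`.
#' @export
family_level_bms <- function(E, partition, prior_alpha = 1,
                             n_samples = 1e6, seed = 1) {
  E <- as.matrix(E)
  ids <- as.integer(colnames(E))
  sizes <- vapply(partition, function(f) length(f$member_ids), 0L)
  if (any(sizes == 0))
    stop("empty family: ",
         paste(vapply(partition[sizes == 0], `[[`, "", "name"),
               collapse = ", "))
  all_members <- sort(unlist(lapply(partition, `[[`, "member_ids")))
  if (!identical(all_members, sort(ids)))
    stop("partition does not cover exactly the evidence columns")
  fam_of <- rep(NA_integer_, length(ids))
  for (fi in seq_along(partition))
    fam_of[ids %in% partition[[fi]]$member_ids] <- fi
  fam_names <- vapply(partition, `[[`, "", "name")

  # per-subject family evidence under the uniform within-family prior
  Ef <- matrix(0, nrow(E), length(partition),
               dimnames = list(rownames(E), fam_names))
  for (fi in seq_along(partition))
    Ef[, fi] <- apply(E[, fam_of == fi, drop = FALSE], 1, log_sum_exp) -
      log(sizes[fi])
  if (length(partition) == 1) {
    fam <- data.frame(family = fam_names, size = sizes, alpha = NA_real_,
                      expected_freq = 1, exceedance = 1)
    post_f <- NULL
  } else {
    post_f <- rfx_bms(Ef, prior_alpha = prior_alpha)
    xp_family <- exceedance_probabilities(post_f, n_samples, seed + 1)
    fam <- data.frame(family = fam_names, size = sizes,
                      alpha = as.numeric(post_f$alpha),
                      expected_freq = as.numeric(post_f$expected_freq),
                      exceedance = as.numeric(xp_family))
  }
  if (ncol(E) == 1) {
    post_m <- list(alpha = setNames(1 + nrow(E), colnames(E)),
                   expected_freq = setNames(1, colnames(E)),
                   assignments = matrix(1, nrow(E), 1))
    xp_model <- setNames(1, colnames(E))
  } else {
    post_m <- rfx_bms(E, prior_alpha = 1)
    xp_model <- exceedance_probabilities(post_m, n_samples, seed)
  }
  structure(list(
    alpha = post_m$alpha,
    expected_freq = post_m$expected_freq,
    exceedance = xp_model,
    assignments = post_m$assignments,
    family = fam,
    family_evidence = Ef,
    family_posterior = post_f,
    fam_of = fam_of,
    n_samples = n_samples, seed = seed),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Family-level random-effects BMS\n")
  print(x$family, digits = 3)
  best <- which.max(x$exceedance)
  cat(sprintf("best single model: %s (exceedance %.3f)\n",
              names(x$exceedance)[best], x$exceedance[best]))
  invisible(x)
}

#' Two-stage winning-model rule
#'
#' Picks the family with the largest family exceedance probability, then
#' the model with the largest model-level exceedance probability within
#' that family. Exact ties are broken toward the lower model id with a
#' warning.
#'
#' @param E Subjects x models log-evidence matrix.
#' @param partition Family partition of the model space.
#' @param ... Passed to [family_level_bms()].
#' @param bms Optional precomputed [family_level_bms()] result for `E`.
#' @return List: `winning_family` (name), `winning_model` (id), `bms`
#'   (the full `bms_result`).
#' @export
select_winning <- function(E, partition, ..., bms = NULL) {
  if (is.null(bms)) bms <- family_level_bms(E, partition, ...)
  wf <- which.max(bms$family$exceedance)
  members <- bms$fam_of == wf
  xp <- bms$exceedance[members]
  ids <- as.integer(names(xp))
  best <- xp == max(xp)
  if (sum(best) > 1)
    warning("exceedance tie within the winning family; choosing model ",
            min(ids[best]))
  list(winning_family = bms$family$family[wf],
       winning_model = min(ids[best]),
       bms = bms)
}
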