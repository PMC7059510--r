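#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling over the corpus's tokens, with symmetric
#' Dirichlet priors (`alpha = 0.1` on document--topic mixtures and
#' `beta = 0.1` on topic--word distributions; the sparse document prior
#' suits short snippets, whose mixtures would otherwise be flattened
#' toward uniform).
#' The sampler runs `iter` full sweeps and the final state is used as the
#' point estimate of the topic--word matrix. All randomness flows from
#' `seed`, so refitting with the same seed reproduces identical topic
#' proportions.
#'
#' @param corpus list of `token_list` objects ([preprocess_corpus()]).
#' @param n_topics number of topics K (>= 2).
#' @param seed integer RNG seed.
#' @param iter Gibbs sweeps (default 200).
#' @param alpha,beta Dirichlet hyperparameters.
#' @return object of class `dhi_lda`: list with `n_topics`, `terms`, `phi`
#'   (K x V topic-word matrix, rows sum to 1), `theta` (D x K fitted
#'   document-topic proportions), `alpha`, `beta`, `seed`, and
#'   `corpus_loglik` (token log-likelihood of the fitted corpus).
#' @export
fit_topic_model <- function(corpus, n_topics = 8L, seed = 1L, iter = 200L,
                            alpha = 0.1, beta = 0.1) {
  n_topics <- as.integer(n_topics)
  stopifnot(n_topics >= 2L)
  lens <- vapply(corpus, function(tl) length(tl$tokens), integer(1))
  if (sum(lens > 0L) < n_topics) {
    stop("too few non-empty documents to fit ", n_topics, " topics",
         call. = FALSE)
  }
  terms <- sort(unique(unlist(lapply(corpus, `[[`, "tokens"),
                              use.names = FALSE)), method = "radix")
  docs <- lapply(corpus, function(tl) {
    match(tl$tokens, terms) - 1L
  })
  set.seed(seed)
  st <- .lda_gibbs_cpp(docs, length(terms), n_topics, alpha, beta,
                       as.integer(iter))
  nwk <- st$nwk; ndk <- st$ndk; nk <- st$nk; nd <- st$nd
  V <- length(terms)
  phi <- t(sweep(nwk + beta, 2L, nk + V * beta, "/"))  # K x V
  colnames(phi) <- terms
  theta <- sweep(ndk + alpha, 1L, nd + n_topics * alpha, "/")
  model <- structure(list(
    n_topics = n_topics, terms = terms, phi = phi, theta = theta,
    alpha = alpha, beta = beta, seed = seed, iter = as.integer(iter)
  ), class = "dhi_lda")
  model$corpus_loglik <- sum(vapply(seq_along(corpus), function(d) {
    .doc_loglik(docs[[d]] + 1L, theta[d, ], phi)
  }, numeric(1)))
  model
}

.doc_loglik <- function(word_idx, theta, phi) {
  if (!length(word_idx)) return(0)
  mix <- as.numeric(theta %*% phi[, word_idx, drop = FALSE])
  sum(log(pmax(mix, .Machine$double.xmin)))
}

#' @export
print.dhi_lda <- function(x, ...) {
  cat(sprintf("<dhi_lda: %d topics over %d terms, %d docs, loglik %.1f>\n",
              x$n_topics, length(x$terms), nrow(x$theta), x$corpus_loglik))
  invisible(x)
}

#' @export
logLik.dhi_lda <- function(object, ...) {
  structure(object$corpus_loglik, class = "logLik",
            df = object$n_topics * length(object$terms))
}

#' Infer topic proportions for a document under a fitted model
#'
#' Deterministic "fold-in": with the topic--word matrix held fixed, the
#' document--topic mixture is estimated by iterating the EM fixed point
#' (responsibilities proportional to `phi[k, w] * theta[k]`, then a
#' Dirichlet-smoothed re-estimate of `theta`). No sampling is involved, so
#' featurization needs no per-snippet seed. Out-of-vocabulary tokens are
#' skipped.
#'
#' @param model a `dhi_lda`.
#' @param tokens a `token_list` or character vector.
#' @param iter fixed-point iterations.
#' @return numeric vector of length `n_topics` summing to 1.
#' @export
infer_topics <- function(model, tokens, iter = 50L) {
  tk <- if (inherits(tokens, "token_list")) tokens$tokens else tokens
  idx <- match(tk, model$terms)
  idx <- idx[!is.na(idx)]
  K <- model$n_topics
  if (!length(idx)) return(rep(1 / K, K))
  phi_w <- model$phi[, idx, drop = FALSE]   # K x n
  theta <- rep(1 / K, K)
  n <- length(idx)
  for (i in seq_len(iter)) {
    q <- phi_w * theta                       # K x n responsibilities
    q <- sweep(q, 2L, pmax(colSums(q), .Machine$double.xmin), "/")
    theta <- (rowSums(q) + model$alpha) / (n + K * model$alpha)
  }
  theta / sum(theta)
}

#' Topic feature block for one snippet
#'
#' For a model with K topics: entries 1..K are the inferred topic
#' proportions, entry K+1 is the population standard deviation of those
#' proportions (`sqrt(mean((p - 1/K)^2))`), and entry K+2 is the
#' document log-likelihood under the model. An empty (or fully
#' out-of-vocabulary) snippet gets uniform proportions, zero SD and zero
#' log-likelihood, with a warning.
#'
#' @param tokens a `token_list` or character vector.
#' @param model a `dhi_lda`.
#' @return named numeric vector of length `n_topics + 2`.
#' @export
topic_features <- function(tokens, model) {
  tk <- if (inherits(tokens, "token_list")) tokens$tokens else tokens
  K <- model$n_topics
  nm <- c(paste0("topic_", seq_len(K)), "topic_sd", "topic_loglik")
  idx <- match(tk, model$terms)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    warning("snippet has no in-vocabulary tokens for the topic model; ",
            "uniform proportions emitted", call. = FALSE)
    return(stats::setNames(c(rep(1 / K, K), 0, 0), nm))
  }
  p <- infer_topics(model, tk)
  ll <- .doc_loglik(idx, p, model$phi)
  stats::setNames(c(p, sqrt(mean((p - mean(p))^2)), ll), nm)
}
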