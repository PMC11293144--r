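#' Linear-chain CRF over BIO tags
#'
#' The CRF scores a tag sequence as the sum of per-position emission scores
#' and pairwise transition scores, including boundary transitions from a
#' virtual `START` state into the first tag and from the last tag into a
#' virtual `STOP` state. The normalised probability of a sequence is its
#' exponentiated score divided by the sum over all possible sequences,
#' computed by the forward algorithm in log space; training minimises the
#' negative log-likelihood, decoding maximises the score by Viterbi.
#'
#' Tag indices 1..K refer to the BIO tag set; the transition matrix is
#' (K+2) x (K+2) with `START = K+1` and `STOP = K+2`.
#'
#' @name crf
NULL

#' CRF parameters
#'
#' @param k_tags Number of BIO tags K.
#' @param init Initial transition score (default 0 for all transitions).
#' @param mask Optional logical (K+2) x (K+2) matrix of allowed transitions;
#'   disallowed entries are fixed at `-Inf`. See [crf_transition_mask()].
#' @return List with `T` ((K+2) x (K+2)), `k_tags`, `start`, `stop`, `mask`.
#' @export
crf_params <- function(k_tags, init = 0, mask = NULL) {
  K <- as.integer(k_tags)
  Tm <- matrix(init, K + 2L, K + 2L)
  Tm[, K + 1L] <- -Inf          # nothing enters START
  Tm[K + 2L, ] <- -Inf          # nothing leaves STOP
  Tm[K + 1L, K + 2L] <- -Inf    # START cannot jump straight to STOP (n >= 1)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == c(K + 2L, K + 2L)))
    Tm[!mask] <- -Inf
  }
  list(T = Tm, k_tags = K, start = K + 1L, stop = K + 2L, mask = mask)
}

#' Hard BIO transition mask
#'
#' Allowed-transition matrix derived from [is_valid_transition()]: forbidden
#' BIO transitions (`O -> I-t`, cross-type `B/I -> I`, `START -> I-t`) are
#' `FALSE`. Masking is optional — by default the CRF is left to learn these
#' constraints from data — but a masked CRF can never decode an invalid
#' sequence.
#'
#' @param schema An `event_schema` or `bio_tagset`.
#' @return Logical (K+2) x (K+2) matrix.
#' @export
crf_transition_mask <- function(schema) {
  ts <- as_tagset(schema)
  states <- c(ts$tags, "START", "STOP")
  K <- length(ts$tags)
  M <- matrix(TRUE, K + 2L, K + 2L, dimnames = list(states, states))
  for (a in states) for (b in states) {
    M[a, b] <- is_valid_transition(a, b, ts)
  }
  M
}

check_emissions <- function(F, params) {
  if (!is.matrix(F) || nrow(F) < 1L) stop("emissions must be a matrix with n >= 1 rows")
  if (ncol(F) != params$k_tags) {
    stop("emission matrix has ", ncol(F), " columns; CRF expects ", params$k_tags)
  }
}

#' Score a tag sequence
#'
#' `score = T[START, y1] + sum_i T[y_i, y_{i+1}] + T[y_n, STOP] + sum_i F[i, y_i]`.
#'
#' @param F n x K emission matrix.
#' @param y Integer tag indices (length n) or character tags (requires
#'   `schema`).
#' @param params From [crf_params()].
#' @param schema Optional schema/tagset to resolve character tags.
#' @return Scalar score.
#' @export
crf_score <- function(F, y, params, schema = NULL) {
  check_emissions(F, params)
  y <- resolve_tags(y, schema)
  n <- nrow(F)
  if (length(y) != n) stop("tag sequence length ", length(y), " != emissions rows ", n)
  s <- params$T[params$start, y[1]] + params$T[y[n], params$stop] +
    sum(F[cbind(seq_len(n), y)])
  if (n > 1L) s <- s + sum(params$T[cbind(y[-n], y[-1L])])
  s
}

resolve_tags <- function(y, schema) {
  if (is.character(y)) {
    if (is.null(schema)) stop("character tags need a schema/tagset")
    ts <- as_tagset(schema)
    y <- unname(ts$index[y])
    if (anyNA(y)) stop("unknown tag in sequence")
  }
  as.integer(y)
}

#' Log-partition function
#'
#' `log sum_{y'} exp(score(F, y'))` over all K^n sequences, by the forward
#' recursion in log space (stable under large emission scales).
#'
#' @inheritParams crf_score
#' @return Scalar log-partition value.
#' @export
crf_log_partition <- function(F, params) {
  check_emissions(F, params)
  K <- params$k_tags; n <- nrow(F)
  Tin <- params$T[seq_len(K), seq_len(K), drop = FALSE]
  a <- params$T[params$start, seq_len(K)] + F[1L, ]
  if (n > 1L) for (i in 2L:n) {
    M <- a + Tin                       # M[p, q] = a[p] + T[p, q]
    mx <- apply(M, 2L, max)
    fin <- is.finite(mx)
    b <- rep(-Inf, K)
    if (any(fin)) {
      b[fin] <- mx[fin] +
        log(colSums(exp(M[, fin, drop = FALSE] -
                          rep(mx[fin], each = K))))
    }
    a <- b + F[i, ]
  }
  logsumexp(a + params$T[seq_len(K), params$stop])
}

crf_forward_backward <- function(F, params) {
  K <- params$k_tags; n <- nrow(F)
  Tin <- params$T[seq_len(K), seq_len(K), drop = FALSE]
  alpha <- matrix(-Inf, n, K)
  alpha[1L, ] <- params$T[params$start, seq_len(K)] + F[1L, ]
  if (n > 1L) for (i in 2L:n) {
    M <- alpha[i - 1L, ] + Tin
    mx <- apply(M, 2L, max)
    fin <- is.finite(mx)
    if (any(fin)) {
      alpha[i, fin] <- mx[fin] +
        log(colSums(exp(M[, fin, drop = FALSE] - rep(mx[fin], each = K)))) +
        F[i, fin]
    }
  }
  beta <- matrix(-Inf, n, K)
  beta[n, ] <- params$T[seq_len(K), params$stop]
  if (n > 1L) for (i in (n - 1L):1L) {
    M <- Tin + rep(F[i + 1L, ] + beta[i + 1L, ], each = K)  # M[p, q]
    mx <- apply(M, 1L, max)
    fin <- is.finite(mx)
    if (any(fin)) {
      beta[i, fin] <- mx[fin] +
        log(rowSums(exp(M[fin, , drop = FALSE] - mx[fin])))
    }
  }
  logZ <- logsumexp(alpha[n, ] + params$T[seq_len(K), params$stop])
  list(alpha = alpha, beta = beta, logZ = logZ)
}

#' Log-probability and negative log-likelihood of a sequence
#'
#' `crf_log_prob` = score minus log-partition (always <= 0);
#' `crf_nll` is its negation, the training loss.
#'
#' @inheritParams crf_score
#' @return Scalar.
#' @export
crf_log_prob <- function(F, y, params, schema = NULL) {
  crf_score(F, y, params, schema) - crf_log_partition(F, params)
}

#' @rdname crf_log_prob
#' @export
crf_nll <- function(F, y, params, schema = NULL) {
  -crf_log_prob(F, y, params, schema)
}

#' Gradient of the negative log-likelihood
#'
#' Expected minus observed sufficient statistics, from forward-backward
#' marginals: `dF = P(tag at i) - 1{y_i}`, and for transitions the expected
#' pairwise counts minus the observed ones (including the START/STOP
#' boundary entries). Masked (`-Inf`) transitions receive zero gradient.
#'
#' @inheritParams crf_score
#' @return List with `nll`, `dF` (n x K) and `dT` ((K+2) x (K+2)).
#' @export
crf_nll_grad <- function(F, y, params, schema = NULL) {
  check_emissions(F, params)
  y <- resolve_tags(y, schema)
  K <- params$k_tags; n <- nrow(F)
  fb <- crf_forward_backward(F, params)
  logZ <- fb$logZ
  gamma <- exp(fb$alpha + fb$beta - logZ)    # n x K marginals
  dF <- gamma
  dF[cbind(seq_len(n), y)] <- dF[cbind(seq_len(n), y)] - 1
  dT <- matrix(0, K + 2L, K + 2L)
  Tin <- params$T[seq_len(K), seq_len(K), drop = FALSE]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    logxi <- fb$alpha[i, ] + Tin +
      rep(F[i + 1L, ] + fb$beta[i + 1L, ], each = K) - logZ
    xi <- exp(logxi)
    dT[seq_len(K), seq_len(K)] <- dT[seq_len(K), seq_len(K)] + xi
    dT[y[i], y[i + 1L]] <- dT[y[i], y[i + 1L]] - 1
  }
  # boundary terms
  dT[params$start, seq_len(K)] <- dT[params$start, seq_len(K)] + gamma[1L, ]
  dT[params$start, y[1L]] <- dT[params$start, y[1L]] - 1
  dT[seq_len(K), params$stop] <- dT[seq_len(K), params$stop] + gamma[n, ]
  dT[y[n], params$stop] <- dT[y[n], params$stop] - 1
  dT[!is.finite(params$T)] <- 0
  list(nll = -(crf_score(F, y, params) - logZ), dF = dF, dT = dT)
}

#' Viterbi decoding
#'
#' Returns a maximum-score tag sequence. Ties are broken toward the lowest
#' tag index at each backtracking step.
#'
#' @inheritParams crf_score
#' @param as_tags If a schema/tagset is given, return character tags.
#' @return Integer tag indices (or character tags), with the attained score
#'   as attribute `score`.
#' @export
crf_viterbi <- function(F, params, schema = NULL, as_tags = !is.null(schema)) {
  check_emissions(F, params)
  K <- params$k_tags; n <- nrow(F)
  Tin <- params$T[seq_len(K), seq_len(K), drop = FALSE]
  delta <- params$T[params$start, seq_len(K)] + F[1L, ]
  back <- matrix(0L, n, K)
  if (n > 1L) for (i in 2L:n) {
    M <- delta + Tin
    bp <- apply(M, 2L, which.max)      # first max = lowest index on ties
    delta <- M[cbind(bp, seq_len(K))] + F[i, ]
    back[i, ] <- bp
  }
  fin <- delta + params$T[seq_len(K), params$stop]
  y <- integer(n)
  y[n] <- which.max(fin)
  if (n > 1L) for (i in n:2L) y[i - 1L] <- back[i, y[i]]
  score <- max(fin)
  if (as_tags) {
    ts <- as_tagset(schema)
    out <- ts$tags[y]
  } else out <- y
  attr(out, "score") <- score
  out
}
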