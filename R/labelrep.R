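#' Label-based representation layers
#'
#' Between the joint encoder and the CRF sit three per-token representations:
#' the sentence encoding `H_S` itself, a label-context attention
#' representation `C` (each token attends over the label encodings with the
#' token as query and the labels as key and value, optionally averaged by
#' 1/N over the N labels), and a label-trigger affinity matrix `A` whose
#' entry (i, j) is `sigmoid(h_S(i)' W h_L(j) + b)` for a learnable
#' interaction matrix `W`. Three separate single-layer affine heads project
#' each to tag space, and the projections are combined as
#' `x = X' + alpha * Xhat + (1 - alpha) * Xtilde`.
#'
#' @name label_representations
NULL

#' Parameters for the label-context attention
#'
#' Single-head scaled dot-product attention with learned square projections:
#' query from `H_S`, key and value from `H_L`, scale `1/sqrt(d)`.
#'
#' @param d Encoding dimension.
#' @param include_scale Divide the attended value sum by the number of labels
#'   N (the literal averaged form; default `TRUE`). With `FALSE` the softmax
#'   -weighted sum is used unaveraged.
#' @param seed Initialisation seed.
#' @return List with `Pq`, `Pk`, `Pv` (d x d) and `include_scale`.
#' @export
lcar_params <- function(d, include_scale = TRUE, seed = 1L) {
  with_seed(seed, list(Pq = init_mat(d, d), Pk = init_mat(d, d),
                       Pv = init_mat(d, d), include_scale = include_scale))
}

#' Parameters for the label-trigger affinity
#'
#' @param d Encoding dimension.
#' @param seed Initialisation seed. `W` is uniform in `±1/sqrt(d)`, `b = 0`.
#' @return List with `W` (d x d) and scalar `b`.
#' @export
ltar_params <- function(d, seed = 1L) {
  with_seed(seed, list(W = init_mat(d, d), b = 0))
}

#' Projection heads to tag space
#'
#' Three separate affine maps, one per representation (no weight sharing, no
#' concatenation): `H_S` (d -> k_tags), `C` (d -> k_tags) and the per-token
#' label-affinity vector (m -> k_tags).
#'
#' @param d Encoding dimension.
#' @param m Number of labels.
#' @param k_tags Size of the BIO tag set (2k + 1).
#' @param seed Initialisation seed.
#' @return List of three heads, each `list(W, b)`.
#' @export
projection_heads <- function(d, m, k_tags, seed = 1L) {
  with_seed(seed, list(
    h1 = list(W = init_mat(d, k_tags), b = rep(0, k_tags)),
    h2 = list(W = init_mat(d, k_tags), b = rep(0, k_tags)),
    h3 = list(W = init_mat(m, k_tags), b = rep(0, k_tags))))
}

#' Label-context attention representation
#'
#' `C_i = (1/N) sum_j a_ij v_j`, where the attention weights `a_ij` are the
#' row-softmax of scaled dot products between the projected query `h_S(i) Pq`
#' and keys `h_L(j) Pk`, and `v_j = h_L(j) Pv`. With `include_scale = FALSE`
#' the 1/N factor is dropped.
#'
#' @param H_S n x d sentence encodings.
#' @param H_L m x d label encodings (m = N >= 1).
#' @param params From [lcar_params()] (identity projections can be passed
#'   directly as `list(Pq = diag(d), ...)`).
#' @return List with `C` (n x d) and `attn` (n x m row-stochastic weights).
#' @export
label_context_attention <- function(H_S, H_L, params) {
  if (nrow(H_L) < 1L) stop("at least one label encoding is required")
  d <- ncol(H_S)
  stopifnot(ncol(H_L) == d)
  Q <- H_S %*% params$Pq
  K <- H_L %*% params$Pk
  V <- H_L %*% params$Pv
  S <- tcrossprod(Q, K) / sqrt(d)
  attn <- softmax_rows(S)
  scale <- if (isTRUE(params$include_scale)) 1 / nrow(H_L) else 1
  list(C = scale * (attn %*% V), attn = attn,
       cache = list(Q = Q, K = K, V = V, attn = attn, scale = scale,
                    H_S = H_S, H_L = H_L))
}

label_context_attention_bwd <- function(dC, cache, params) {
  d <- ncol(cache$H_S)
  attn <- cache$attn; sc <- cache$scale
  dattn <- sc * tcrossprod(dC, cache$V)
  dV <- sc * crossprod(attn, dC)
  dS <- attn * (dattn - rowSums(dattn * attn))
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- crossprod(dS, cache$Q) / sqrt(d)
  list(dH_S = tcrossprod(dQ, params$Pq),
       dH_L = tcrossprod(dK, params$Pk) + tcrossprod(dV, params$Pv),
       dPq = crossprod(cache$H_S, dQ),
       dPk = crossprod(cache$H_L, dK),
       dPv = crossprod(cache$H_L, dV))
}

#' Label-trigger affinity
#'
#' `A[i, j] = sigmoid(h_S(i)' W h_L(j) + b)`: a bilinear interaction score
#' between every sentence token and every label, squashed to (0, 1).
#'
#' @param H_S n x d sentence encodings.
#' @param H_L m x d label encodings.
#' @param params From [ltar_params()]: `W` (d x d), scalar `b`.
#' @return n x m matrix with entries strictly in (0, 1).
#' @export
label_affinity <- function(H_S, H_L, params) {
  if (!all(is.finite(params$W)) || !is.finite(params$b)) {
    stop("non-finite affinity parameters")
  }
  stopifnot(ncol(H_S) == nrow(params$W), ncol(H_L) == ncol(params$W))
  Z <- H_S %*% tcrossprod(params$W, H_L) + params$b
  stats::plogis(Z)
}

label_affinity_bwd <- function(dA, A, H_S, H_L, params) {
  dZ <- dA * A * (1 - A)
  list(dH_S = dZ %*% H_L %*% t(params$W),
       dH_L = crossprod(dZ, H_S) %*% params$W,
       dW = crossprod(H_S, dZ) %*% H_L,
       db = sum(dZ))
}

#' Project the three representations to tag space
#'
#' Each head is an affine map of its own input only.
#'
#' @param H_S,C n x d matrices; `A` n x m affinity matrix.
#' @param heads From [projection_heads()].
#' @return List of `Xp` (from `H_S`), `Xh` (from `C`), `Xt` (from `A`), each
#'   n x k_tags.
#' @export
project_emissions <- function(H_S, C, A, heads) {
  stopifnot(ncol(H_S) == nrow(heads$h1$W), ncol(C) == nrow(heads$h2$W),
            ncol(A) == nrow(heads$h3$W))
  n <- nrow(H_S)
  list(Xp = H_S %*% heads$h1$W + row_bcast(heads$h1$b, n),
       Xh = C %*% heads$h2$W + row_bcast(heads$h2$b, n),
       Xt = A %*% heads$h3$W + row_bcast(heads$h3$b, n))
}

#' Combine projected representations
#'
#' `x = Xp + alpha * Xh + (1 - alpha) * Xt`. The sentence projection enters
#' unweighted as a residual base. Ablation switches drop terms: without the
#' label-context term `x = Xp + Xt`; without the affinity term
#' `x = Xp + alpha * Xh`; without both `x = Xp`.
#'
#' @param Xp,Xh,Xt n x k_tags matrices of equal shape.
#' @param alpha Mixing weight, strictly in (0, 1).
#' @param use_lcar,use_ltar Ablation switches (default both `TRUE`).
#' @return n x k_tags combined emission matrix.
#' @export
combine_emissions <- function(Xp, Xh, Xt, alpha = 0.5,
                              use_lcar = TRUE, use_ltar = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)")
  }
  stopifnot(all(dim(Xp) == dim(Xh)), all(dim(Xp) == dim(Xt)))
  w <- combine_weights(alpha, use_lcar, use_ltar)
  Xp + w[1] * Xh + w[2] * Xt
}

# (weight on Xh, weight on Xt) under the ablation switches
combine_weights <- function(alpha, use_lcar, use_ltar) {
  if (use_lcar && use_ltar) c(alpha, 1 - alpha)
  else if (!use_lcar && use_ltar) c(0, 1)
  else if (use_lcar && !use_ltar) c(alpha, 0)
  else c(0, 0)
}

#' Full label-representation forward pass
#'
#' Composes attention, affinity, projection and combination into the emission
#' matrix, caching intermediates for [lsrl_backward()].
#'
#' @param H_S,H_L Encodings.
#' @param params List with `lcar`, `ltar`, `heads`.
#' @param alpha Mixing weight.
#' @param use_lcar,use_ltar Ablation switches.
#' @return List with `x` (n x k_tags emissions), intermediates `C`, `A`,
#'   `Xp`, `Xh`, `Xt`, and `cache`.
#' @export
lsrl_forward <- function(H_S, H_L, params, alpha = 0.5,
                         use_lcar = TRUE, use_ltar = TRUE) {
  la <- label_context_attention(H_S, H_L, params$lcar)
  A <- label_affinity(H_S, H_L, params$ltar)
  pr <- project_emissions(H_S, la$C, A, params$heads)
  x <- combine_emissions(pr$Xp, pr$Xh, pr$Xt, alpha, use_lcar, use_ltar)
  list(x = x, C = la$C, A = A, Xp = pr$Xp, Xh = pr$Xh, Xt = pr$Xt,
       attn = la$attn,
       cache = list(lcar = la$cache, A = A, H_S = H_S, H_L = H_L,
                    alpha = alpha, use_lcar = use_lcar, use_ltar = use_ltar))
}

#' Backward pass through the label-representation layers
#'
#' @param dx Gradient of the loss w.r.t. the combined emissions.
#' @param fw Result of [lsrl_forward()].
#' @param params Same parameter list as the forward pass.
#' @return List with `dH_S`, `dH_L`, and `grads` (named: `lcar.Pq`,
#'   `lcar.Pk`, `lcar.Pv`, `ltar.W`, `ltar.b`, `h1.W`, `h1.b`, `h2.W`,
#'   `h2.b`, `h3.W`, `h3.b`).
#' @export
lsrl_backward <- function(dx, fw, params) {
  cc <- fw$cache
  w <- combine_weights(cc$alpha, cc$use_lcar, cc$use_ltar)
  dXp <- dx
  dXh <- w[1] * dx
  dXt <- w[2] * dx
  H_S <- cc$H_S; H_L <- cc$H_L
  g <- list()
  # head 1 (sentence)
  g[["h1.W"]] <- crossprod(H_S, dXp); g[["h1.b"]] <- colSums(dXp)
  dH_S <- tcrossprod(dXp, params$heads$h1$W)
  # head 2 (context attention)
  g[["h2.W"]] <- crossprod(fw$C, dXh); g[["h2.b"]] <- colSums(dXh)
  dC <- tcrossprod(dXh, params$heads$h2$W)
  lb <- label_context_attention_bwd(dC, cc$lcar, params$lcar)
  dH_S <- dH_S + lb$dH_S
  dH_L <- lb$dH_L
  g[["lcar.Pq"]] <- lb$dPq; g[["lcar.Pk"]] <- lb$dPk; g[["lcar.Pv"]] <- lb$dPv
  # head 3 (affinity)
  g[["h3.W"]] <- crossprod(fw$A, dXt); g[["h3.b"]] <- colSums(dXt)
  dA <- tcrossprod(dXt, params$heads$h3$W)
  ab <- label_affinity_bwd(dA, fw$A, H_S, H_L, params$ltar)
  dH_S <- dH_S + ab$dH_S
  dH_L <- dH_L + ab$dH_L
  g[["ltar.W"]] <- ab$dW; g[["ltar.b"]] <- ab$db
  list(dH_S = dH_S, dH_L = dH_L, grads = g)
}
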