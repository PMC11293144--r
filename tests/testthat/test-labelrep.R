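id_lcar <- function(d, include_scale = TRUE) {
  list(Pq = diag(d), Pk = diag(d), Pv = diag(d), include_scale = include_scale)
}

test_that("single-label attention collapses to that label's encoding", {
  d <- 3L
  H_S <- matrix(rnorm(6), 2L, d)
  H_L <- matrix(c(1, 2, 3), 1L, d)
  out <- label_context_attention(H_S, H_L, id_lcar(d))
  expect_equal(out$attn, matrix(1, 2L, 1L))
  expect_equal(out$C, rbind(H_L[1, ], H_L[1, ]))   # 1/N = 1
})

test_that("identical label rows make C their common value over N", {
  d <- 2L; N <- 4L
  H_S <- matrix(rnorm(6), 3L, d)
  v <- c(0.5, -1)
  H_L <- matrix(rep(v, each = N), N, d)
  out <- label_context_attention(H_S, H_L, id_lcar(d))
  expect_equal(out$C, matrix(rep(v / N, each = 3L), 3L, d), tolerance = 1e-12)
  # without the 1/N factor the value itself is recovered
  out2 <- label_context_attention(H_S, H_L, id_lcar(d, include_scale = FALSE))
  expect_equal(out2$C, matrix(rep(v, each = 3L), 3L, d), tolerance = 1e-12)
})

test_that("hand-computed 2-label attention instance matches", {
  # queries (1,0); keys/values (1,0), (0,1); scores (1/sqrt(2), 0)
  H_S <- matrix(c(1, 0), 1L, 2L)
  H_L <- rbind(c(1, 0), c(0, 1))
  out <- label_context_attention(H_S, H_L, id_lcar(2L))
  a1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(out$attn, matrix(c(a1, 1 - a1), 1L, 2L), tolerance = 1e-6)
  expect_equal(out$attn[1, 1], 0.6698, tolerance = 1e-4)
  expect_equal(out$C, matrix(c(a1, 1 - a1) / 2, 1L, 2L), tolerance = 1e-6)
  expect_equal(out$C[1, ], c(0.3349, 0.1651), tolerance = 1e-4)
})

test_that("attention rows always sum to one", {
  withr::local_seed(11)
  for (r in 1:20) {
    n <- sample(1:6, 1L); m <- sample(1:5, 1L); d <- sample(2:5, 1L)
    prm <- lcar_params(d, seed = r)
    out <- label_context_attention(matrix(rnorm(n * d) * 3, n, d),
                                   matrix(rnorm(m * d) * 3, m, d), prm)
    expect_equal(rowSums(out$attn), rep(1, n), tolerance = 1e-12)
  }
})

test_that("affinity is sigmoid of the bilinear form", {
  # W = 0, b = 0 gives exactly 1/2 everywhere
  H_S <- matrix(rnorm(8), 4L, 2L); H_L <- matrix(rnorm(6), 3L, 2L)
  A <- label_affinity(H_S, H_L, list(W = matrix(0, 2, 2), b = 0))
  expect_equal(A, matrix(0.5, 4L, 3L))
  # closed-form single entry
  A2 <- label_affinity(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2),
                       list(W = rbind(c(0, 2), c(0, 0)), b = 0))
  expect_equal(A2[1, 1], plogis(2))
  expect_equal(A2[1, 1], 0.880797, tolerance = 1e-6)
})

test_that("vectorized affinity equals the naive double loop", {
  withr::local_seed(12)
  d <- 3L
  H_S <- matrix(rnorm(4 * d), 4L, d)
  H_L <- matrix(rnorm(3 * d), 3L, d)
  prm <- ltar_params(d, seed = 5L); prm$b <- 0.3
  A <- label_affinity(H_S, H_L, prm)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(A[i, j],
                 plogis(drop(H_S[i, ] %*% prm$W %*% H_L[j, ]) + prm$b),
                 tolerance = 1e-10)
  }
  expect_true(all(A > 0 & A < 1))
  # A is monotone increasing in b
  prm2 <- prm; prm2$b <- prm$b + 1
  expect_true(all(label_affinity(H_S, H_L, prm2) > A))
  expect_error(label_affinity(H_S, H_L, list(W = matrix(NaN, d, d), b = 0)),
               "finite")
})

test_that("projection heads are independent affine maps", {
  withr::local_seed(13)
  d <- 4L; m <- 3L; kt <- 5L; n <- 2L
  heads <- projection_heads(d, m, kt, seed = 2L)
  heads$h1$b <- rnorm(kt); heads$h2$b <- rnorm(kt); heads$h3$b <- rnorm(kt)
  z <- function(nr, nc) matrix(0, nr, nc)
  pr0 <- project_emissions(z(n, d), z(n, d), z(n, m), heads)
  for (h in 1:3) {
    expect_equal(pr0[[h]],
                 matrix(heads[[h]]$b, n, kt, byrow = TRUE))
  }
  # linearity: doubling an input doubles (output - bias)
  H_S <- matrix(rnorm(n * d), n, d)
  pr1 <- project_emissions(H_S, z(n, d), z(n, m), heads)
  pr2 <- project_emissions(2 * H_S, z(n, d), z(n, m), heads)
  b1 <- matrix(heads$h1$b, n, kt, byrow = TRUE)
  expect_equal(pr2$Xp - b1, 2 * (pr1$Xp - b1), tolerance = 1e-12)
  # naive oracle
  C <- matrix(rnorm(n * d), n, d); A <- matrix(runif(n * m), n, m)
  pr <- project_emissions(H_S, C, A, heads)
  for (i in seq_len(n)) {
    expect_equal(pr$Xh[i, ], drop(C[i, ] %*% heads$h2$W) + heads$h2$b,
                 tolerance = 1e-10)
    expect_equal(pr$Xt[i, ], drop(A[i, ] %*% heads$h3$W) + heads$h3$b,
                 tolerance = 1e-10)
  }
  expect_error(project_emissions(H_S, C, A[, 1:2], heads), "")
})

test_that("combination follows the alpha-weighted residual formula", {
  Xp <- matrix(c(1, 1), 1L); Xh <- matrix(c(2, 0), 1L); Xt <- matrix(c(0, 2), 1L)
  expect_equal(combine_emissions(Xp, Xh, Xt, alpha = 0.3),
               matrix(c(1.6, 2.4), 1L))
  # zero label terms preserve the residual base
  z <- matrix(0, 1L, 2L)
  expect_equal(combine_emissions(Xp, z, z, 0.7), Xp)
  # alpha + (1 - alpha) = 1
  Z <- matrix(c(3, -1), 1L)
  expect_equal(combine_emissions(Xp, Z, Z, 0.5), Xp + Z)
  expect_error(combine_emissions(Xp, Xh, Xt, alpha = 0), "alpha")
  expect_error(combine_emissions(Xp, Xh, Xt, alpha = 1), "alpha")
})

test_that("derivative in alpha equals Xh - Xt by finite differences", {
  withr::local_seed(14)
  Xp <- matrix(rnorm(6), 2L); Xh <- matrix(rnorm(6), 2L); Xt <- matrix(rnorm(6), 2L)
  a <- 0.4; eps <- 1e-6
  num <- (combine_emissions(Xp, Xh, Xt, a + eps) -
            combine_emissions(Xp, Xh, Xt, a - eps)) / (2 * eps)
  expect_equal(num, Xh - Xt, tolerance = 1e-5)
})

test_that("analytic gradients through the full label-representation stack
           match central finite differences", {
  withr::local_seed(15)
  n <- 2L; m <- 2L; d <- 3L; kt <- 4L
  H_S <- matrix(rnorm(n * d), n, d)
  H_L <- matrix(rnorm(m * d), m, d)
  params <- list(lcar = lcar_params(d, seed = 21L),
                 ltar = ltar_params(d, seed = 22L),
                 heads = projection_heads(d, m, kt, seed = 23L))
  R <- matrix(rnorm(n * kt), n, kt)
  loss <- function(p, HS = H_S, HL = H_L) {
    sum(lsrl_forward(HS, HL, p, alpha = 0.4)$x * R)
  }
  fw <- lsrl_forward(H_S, H_L, params, alpha = 0.4)
  bk <- lsrl_backward(R, fw, params)
  eps <- 1e-6
  leaf <- list(c("lcar", "Pq"), c("lcar", "Pk"), c("lcar", "Pv"),
               c("ltar", "W"), c("ltar", "b"),
               c("heads", "h1", "W"), c("heads", "h2", "W"),
               c("heads", "h3", "W"), c("heads", "h1", "b"))
  gname <- c("lcar.Pq", "lcar.Pk", "lcar.Pv", "ltar.W", "ltar.b",
             "h1.W", "h2.W", "h3.W", "h1.b")
  for (li in seq_along(leaf)) {
    path <- leaf[[li]]
    cur <- params[[path]]
    for (i in seq_len(min(4L, length(cur)))) {
      p2 <- params
      p2[[path]][i] <- cur[i] + eps
      up <- loss(p2)
      p2[[path]][i] <- cur[i] - eps
      dn <- loss(p2)
      expect_equal(bk$grads[[gname[li]]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4,
                   label = paste("grad", gname[li], i))
    }
  }
  # and w.r.t. the encodings themselves
  for (i in seq_along(H_S)) {
    H2 <- H_S; H2[i] <- H2[i] + eps; up <- loss(params, HS = H2)
    H2[i] <- H_S[i] - eps; dn <- loss(params, HS = H2)
    expect_equal(bk$dH_S[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
  for (i in seq_along(H_L)) {
    H2 <- H_L; H2[i] <- H2[i] + eps; up <- loss(params, HL = H2)
    H2[i] <- H_L[i] - eps; dn <- loss(params, HL = H2)
    expect_equal(bk$dH_L[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("ablation switches drop exactly their additive term", {
  withr::local_seed(16)
  n <- 3L; m <- 2L; d <- 4L; kt <- 5L
  H_S <- matrix(rnorm(n * d), n, d); H_L <- matrix(rnorm(m * d), m, d)
  params <- list(lcar = lcar_params(d, seed = 1L), ltar = ltar_params(d, seed = 2L),
                 heads = projection_heads(d, m, kt, seed = 3L))
  full <- lsrl_forward(H_S, H_L, params, alpha = 0.5)
  no_lcar <- lsrl_forward(H_S, H_L, params, alpha = 0.5, use_lcar = FALSE)
  no_ltar <- lsrl_forward(H_S, H_L, params, alpha = 0.5, use_ltar = FALSE)
  none <- lsrl_forward(H_S, H_L, params, alpha = 0.5,
                       use_lcar = FALSE, use_ltar = FALSE)
  expect_equal(no_lcar$x, full$Xp + full$Xt)
  expect_equal(no_ltar$x, full$Xp + 0.5 * full$Xh)
  expect_equal(none$x, full$Xp)
  # with both label terms off, emissions ignore H_L entirely
  H_L2 <- H_L + matrix(rnorm(m * d), m, d)
  none2 <- lsrl_forward(H_S, H_L2, params, alpha = 0.5,
                        use_lcar = FALSE, use_ltar = FALSE)
  expect_equal(none2$x, none$x)
})
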