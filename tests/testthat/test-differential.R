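test_that("welch_t matches the closed form and stats::t.test", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_lt(abs(res$t - 3.674), 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_lt(abs(res$p - 0.0214), 1e-3)

  # independent reference: stats::t.test on random draws
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = 0.5)
      ours <- welch_t(a, b)
      ref <- t.test(b, a, var.equal = FALSE)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("welch_t degenerate and symmetry behavior", {
  same <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 3, 2); b <- c(5, 4, 7)
  fwd <- welch_t(a, b); rev <- welch_t(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)

  # shift invariance and scale equivariance of the p-value
  expect_equal(welch_t(a + 10, b + 10)$p, fwd$p, tolerance = 1e-12)
  expect_equal(welch_t(a * 3, b * 3)$p, fwd$p, tolerance = 1e-12)
  expect_equal(welch_t(a * 3, b * 3)$t, fwd$t, tolerance = 1e-12)

  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("variance prior fit recovers simulated hyperparameters", {
  # all variances equal -> degenerate prior
  flat <- fit_variance_prior(rep(2.5, 100), residual_df = 10)
  expect_equal(flat$d0, Inf)
  expect_equal(flat$s0_sq, 2.5, tolerance = 1e-6)

  # simulate s^2 ~ s0^2 * (chisq_d0-scaled prior) x sampling noise and refit
  d0_true <- 4; s0_true <- 1; df <- 10
  errs <- vapply(1:5, function(s) {
    s2 <- withr::with_seed(100 + s, {
      sigma2 <- d0_true * s0_true / rchisq(10000, d0_true)
      sigma2 * rchisq(10000, df) / df
    })
    fit <- fit_variance_prior(s2, df)
    abs(fit$d0 - d0_true) / d0_true
  }, numeric(1))
  expect_true(all(errs < 0.2))

  # agreement with the established moderated-variance fit (independent route)
  s2 <- withr::with_seed(7, (4 * 1 / rchisq(2000, 4)) * rchisq(2000, 10) / 10)
  ours <- fit_variance_prior(s2, 10)
  ref <- limma::fitFDist(s2, df1 = 10)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)

  expect_error(fit_variance_prior(rep(1, 5), 10), ">= 10")
})

test_that("differential_expression is calibrated under the null", {
  cfg <- synthetic_config(n_genes = 2000, n_ligands = 100, n_receptors = 100,
                          n_pairs = 200, frac_de_ligands = 0,
                          frac_de_receptors = 0, frac_de_background = 0,
                          seed = 77)
  st <- generate_two_tissue_study(cfg)
  de <- differential_expression(st$blood)
  frac <- mean(de$p_value < 0.05)
  # binomial 99% envelope around 0.05 at m = 2000
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 2000))
  expect_true(all(de$adj_p >= de$p_value - 1e-15))
  expect_true(all((de$direction == "up") == (de$log2fc > 0), na.rm = TRUE))
})

test_that("overwhelming planted signal attains the smallest p-value", {
  withr::with_seed(5, {
    vals <- matrix(rnorm(50 * 22, 8, 0.1), 50)
    vals[17, 12:22] <- vals[17, 12:22] + 3  # planted effect in OA
  })
  st <- make_study(vals, rep(c("HC", "OA"), c(11, 11)), tissue = "SY")
  for (method in c("welch", "moderated")) {
    de <- differential_expression(st, method = method)
    expect_equal(de$gene[which.min(de$p_value)], "G017")
    expect_equal(de$direction[17], "up")
  }
})

test_that("constant matrix yields t = 0, p = 1, log2fc = 0 everywhere", {
  st <- make_study(matrix(5, 10, 6), rep(c("HC", "OA"), each = 3))
  de <- differential_expression(st)
  expect_true(all(de$t_stat == 0))
  expect_true(all(de$p_value == 1))
  expect_true(all(de$log2fc == 0))
})

test_that("moderated t matches limma's moderated statistic", {
  # heteroscedastic genes (true variances from a scaled inverse chi-square)
  # so the variance prior is informative rather than degenerate
  withr::with_seed(13, {
    n_genes <- 300; n <- 17
    sigma2 <- 4 * 0.25 / rchisq(n_genes, 4)
    vals <- matrix(rnorm(n_genes * n, 8, sqrt(sigma2)), n_genes, n)
  })
  st <- make_study(vals, rep(c("HC", "OA"), c(8, 9)))
  de <- differential_expression(st, method = "moderated")
  design <- stats::model.matrix(~group, data = st$samples)
  fit <- limma::eBayes(limma::lmFit(as.matrix(st$expr[, -1]), design))
  expect_equal(de$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(unique(de$df), unname(fit$df.total[1]), tolerance = 1e-6)
})

test_that("degenerate prior (d0 = Inf) gives every gene the prior variance", {
  prior <- fit_variance_prior(rep(1.7, 100), residual_df = 9)
  expect_equal(prior$d0, Inf)
  expect_equal(prior$s0_sq, 1.7, tolerance = 1e-8)
  # posterior variance (d0*s0^2 + df*s^2)/(d0 + df) -> s0^2 as d0 -> Inf
  s2 <- seq(0.1, 3, length.out = 10)
  post_big_d0 <- (1e12 * prior$s0_sq + 9 * s2) / (1e12 + 9)
  expect_equal(post_big_d0, rep(prior$s0_sq, 10), tolerance = 1e-9)
})

test_that("filter_degs applies a strict threshold on the chosen column", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    p_value = c(0.04, 0.05, 0.010, 0.2),
    adj_p = c(0.16, 0.20, 0.04, 0.4),
    direction = c("up", "down", "up", "down")
  )
  expect_equal(filter_degs(de, 0.05)$gene, c("a", "c"))
  # p exactly at alpha is excluded (strict <)
  expect_false("b" %in% filter_degs(de, 0.05)$gene)
  expect_equal(filter_degs(de, 0.05, use_adjusted = TRUE)$gene, "c")
  expect_equal(nrow(filter_degs(de[0, ], 0.05)), 0)
  expect_error(filter_degs(de, 1), "alpha")

  # random table equals a brute-force row scan
  rt <- withr::with_seed(3, tibble::tibble(
    gene = sprintf("g%03d", 1:200),
    p_value = runif(200), adj_p = pmin(1, runif(200) * 2),
    direction = sample(c("up", "down"), 200, TRUE)))
  expect_equal(filter_degs(rt, 0.31)$gene, rt$gene[rt$p_value < 0.31])
})

test_that("volcano annotations select top genes per direction with tie rules", {
  de <- differential_expression(random_study(200, 10, 12, seed = 23))
  v <- volcano_annotations(de, top_n = 20)
  expect_equal(sum(v$label), 20)
  expect_equal(v$neg_log10_p, -log10(v$p_value))
  # brute-force selection oracle
  for (dir in c("up", "down")) {
    sub <- de[de$direction == dir & !is.na(de$direction), ]
    ord <- sub[order(sub$p_value, -abs(sub$log2fc), sub$gene), ]
    expect_setequal(v$gene[v$label & v$direction == dir],
                    head(ord$gene, 10))
  }

  # clamped when a side has fewer genes than requested
  small <- tibble::tibble(
    gene = c("u1", "u2", "u3", "d1"),
    log2fc = c(1, 2, 3, -1), p_value = c(0.01, 0.02, 0.03, 0.01),
    adj_p = c(0.04, 0.04, 0.04, 0.04),
    direction = c("up", "up", "up", "down")
  )
  vs <- volcano_annotations(small, top_n = 20)
  expect_equal(sum(vs$label), 4)

  v0 <- volcano_annotations(de, top_n = 0)
  expect_equal(sum(v0$label), 0)
  expect_true(all(c("log2fc", "neg_log10_p") %in% names(v0)))
})

test_that("BH adjustment within DE tables matches the step-up definition", {
  # brute-force step-up on all permutations of <= 6 p-values
  brute_bh <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    }
    q
  }
  base <- c(0.01, 0.3, 0.04, 0.9, 0.2, 0.001)
  perms <- withr::with_seed(2, replicate(30, sample(base), simplify = FALSE))
  for (p in perms) {
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # monotone in raw p
  de <- differential_expression(random_study(100, 4, 4, seed = 2))
  ord <- order(de$p_value)
  expect_true(all(diff(de$adj_p[ord]) >= -1e-15))
})

test_that("planted signal at the study's power conditions is well detected", {
  # effect 1 log2 unit, sigma 0.5, blood cohort sizes: sensitivity > 0.9
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- synthetic_config(n_genes = 300, n_ligands = 30, n_receptors = 30,
                            n_pairs = 60, effect_log2 = 1, sigma = 0.5,
                            seed = 400 + s)
    st <- generate_two_tissue_study(cfg)
    de <- differential_expression(st$blood)
    degs <- filter_degs(de, 0.05)
    planted <- st$truth$de$gene[st$truth$de$tissue == "BL"]
    hits <- hits + length(intersect(planted, degs$gene))
    total <- total + length(planted)
  }
  expect_gt(hits / total, 0.9)
})
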