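test_that("the count transform is normalization-invariant and stabilizing", {
  cnt <- matrix(c(0, 4, 10, 0, 4, 10), 3, 2)
  tr <- vst_like_transform(cnt, sf = c(1, 1))
  expect_equal(tr[1, 1], 0)
  expect_equal(tr[, 1], tr[, 2])
  # scaling a sample by its size factor leaves transformed values unchanged
  sc <- cnt
  sc[, 2] <- sc[, 2] * 4
  expect_equal(vst_like_transform(sc, sf = c(1, 4)),
               vst_like_transform(cnt, sf = c(1, 1)))
  # NB mean-variance slope is flattened by the transform
  set.seed(8)
  base <- rlnorm(300, 4, 1.5)
  raw <- matrix(rnbinom(300 * 40, mu = rep(base, 40), size = 10), 300, 40)
  slope <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    keep <- mu > 0 & v > 0
    unname(coef(lm(log10(v[keep]) ~ log10(mu[keep])))[2])
  }
  expect_lt(slope(vst_like_transform(raw, sf = rep(1, 40))), slope(raw))
})

test_that("soft power selection finds structure and falls back on noise", {
  expr <- make_block_expr(2, graded = TRUE)
  pick <- pick_soft_power(expr)
  expect_gte(pick$power, 1)
  expect_gte(pick$r2[as.character(pick$power)], 0.8)
  expect_true(pick$reached_target)
  expect_identical(pick, pick_soft_power(expr))  # deterministic
  set.seed(9)
  noise <- matrix(rnorm(37 * 300), 37,
                  dimnames = list(NULL, paste0("g", 1:300)))
  expect_warning(pn <- pick_soft_power(noise), "max-R2")
  expect_false(pn$reached_target)
  expect_error(pick_soft_power(matrix(1, 30, 10)), "constant")
})

test_that("TOM is a unit-diagonal similarity bounded by [0, 1]", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(25 * 60), 25)
    adj <- abs(cor(x))^6
    tom <- tom_similarity(adj)
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, ncol(adj)))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    # overlap of a gene with itself dominates any partner
    expect_true(all(tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("planted modules are recovered and noise stays unassigned", {
  for (seed in 1:3) {
    expr <- make_block_expr(seed)
    ms <- detect_modules(expr, power = 7)
    expect_gte(mclust::adjustedRandIndex(ms$assignments,
                                         attr(expr, "truth")), 0.9)
    expect_equal(max(ms$assignments), 3)
  }
  set.seed(4)
  noise <- matrix(rnorm(37 * 300), 37,
                  dimnames = list(NULL, paste0("g", 1:300)))
  msn <- detect_modules(noise, power = 6)
  expect_gte(mean(msn$assignments == 0), 0.95)
  # min_size above any block leaves everything unassigned
  expr <- make_block_expr(5)
  ms_big <- detect_modules(expr, power = 7, min_size = 100)
  expect_true(all(ms_big$assignments == 0))
})

test_that("eigengenes are oriented first PCs with maximal variance", {
  set.seed(12)
  profile <- rnorm(30)
  same <- sapply(1:5, function(i) profile)
  colnames(same) <- paste0("g", 1:5)
  e <- module_eigengene(same, 1:5)
  expect_equal(abs(cor(e, profile)), 1)
  expect_gte(mean(cor(e, same)), 0)
  # sign flip of the input flips the eigengene with it (orientation rule)
  expect_equal(module_eigengene(-same, 1:5), -e)
  # stable under sample reordering
  perm <- sample(30)
  expect_equal(module_eigengene(same[perm, ], 1:5), e[perm])
  expect_error(module_eigengene(same, 1), ">= 2")
  # first PC beats random unit projections on variance explained
  x <- scale(matrix(rnorm(30 * 8), 30) + rnorm(30))
  e2 <- module_eigengene(x, 1:8)
  ve <- function(v) sum(cor(v, x)^2)
  rand <- replicate(1000, {
    u <- rnorm(30)
    ve(u)
  })
  expect_gte(ve(e2), max(rand))
})

test_that("module-trait correlation p-values match cor.test", {
  set.seed(14)
  eg <- matrix(rnorm(27 * 2), 27, dimnames = list(NULL, c("M1", "M2")))
  traits <- data.frame(BW = rnorm(27), PLV = rnorm(27))
  traits$BW[3] <- NA
  pop <- rep(c("Tibetan", "Han"), c(13, 14))
  got <- module_trait_association(eg, traits, pop)
  for (j in 1:2) {
    ct <- cor.test(eg[, j], traits$PLV)
    expect_equal(got$r_PLV[j], unname(ct$estimate))
    expect_equal(got$p_PLV[j], ct$p.value)
    ok <- !is.na(traits$BW)
    ct2 <- cor.test(eg[ok, j], traits$BW[ok])
    expect_equal(got$p_BW[j], ct2$p.value)
    ct3 <- cor.test(eg[, j], as.numeric(factor(pop)) - 1)
    expect_equal(got$p_pop[j], ct3$p.value)
  }
  # closed form: r = 0.5, n = 27 -> t = 2.887, p ~ 0.0078
  r <- 0.5
  n <- 27
  p_closed <- 2 * pt(-r * sqrt((n - 2) / (1 - r^2)), n - 2)
  expect_equal(p_closed, 0.0078, tolerance = 0.01)
  # trait identical to the eigengene
  tr2 <- data.frame(BW = eg[, 1])
  got2 <- module_trait_association(eg, tr2, pop)
  expect_equal(got2$r_BW[1], 1)
  expect_lt(got2$p_BW[1], 1e-20)
})

test_that("the effective trait number hits its limiting cases and bounds", {
  id12 <- diag(12)
  m <- effective_trait_number(id12)
  expect_equal(m$meff, 12)
  expect_equal(m$trait_alpha, 0.05 / 12)
  ones <- matrix(1, 12, 12)
  m1 <- effective_trait_number(ones)
  expect_equal(m1$meff, 1)
  expect_equal(m1$trait_alpha, 0.05)
  # four independent blocks of three perfectly correlated traits -> 4
  blk <- kronecker(diag(4), matrix(1, 3, 3))
  m4 <- effective_trait_number(blk)
  expect_equal(m4$meff, 4)
  expect_equal(m4$trait_alpha, 0.0125)
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rnorm(12 * 30), 12)
    C <- cov2cor(tcrossprod(A))
    mm <- effective_trait_number(C)
    expect_gte(mm$meff, 1 - 1e-9)
    expect_lte(mm$meff, 12 + 1e-9)
  }
  expect_error(effective_trait_number(matrix(c(1, 0.5, 0.2, 1), 2, 2)),
               "symmetric")
})

test_that("SDM, key-module, and overlap rules behave per definition", {
  expr <- make_block_expr(6)
  ms <- detect_modules(expr, power = 7)
  n_mod <- max(ms$assignments)
  expect_gte(n_mod, 2)
  stats <- data.frame(module = paste0("M", seq_len(n_mod)),
                      p_pop = c(0.2, rep(0.01, n_mod - 1)),
                      min_trait_p = c(0.001, 0.002,
                                      rep(0.3, n_mod - 2)))
  m1_genes <- names(ms$assignments)[ms$assignments == 1]
  flagged <- flag_sdm_and_key(stats, ms, deg_genes = m1_genes,
                              universe_size = 300, meff = 4)
  expect_false(flagged$is_sdm[1])   # population p too large
  expect_true(flagged$is_sdm_05[2] && flagged$is_sdm_meff[2])
  # module identical to the DEG set has the smallest overlap p
  expect_equal(which.min(flagged$overlap_p), 1L)
  expect_equal(flagged$deg_overlap[1], length(m1_genes))
  # key = SDM with lexicographically smallest (trait p, overlap p)
  expect_equal(flagged$module[flagged$is_key], "M2")
  # empty DEG set -> overlap p = 1 everywhere
  fl0 <- flag_sdm_and_key(stats, ms, deg_genes = character(0),
                          universe_size = 300, meff = 4)
  expect_true(all(fl0$overlap_p == 1))
})

test_that("hub genes require all three criteria, with ties included", {
  set.seed(30)
  n <- 40
  lat <- rnorm(n)
  w <- c(0.99, 0.95, 0.9, 0.9, seq(0.85, 0.7, length.out = 26))
  expr <- sapply(w, function(wi) wi * lat + sqrt(1 - wi^2) * rnorm(n))
  # two exactly duplicated profiles force a degree tie
  expr[, 4] <- expr[, 3]
  colnames(expr) <- paste0("g", seq_along(w))
  expr <- cbind(expr, matrix(rnorm(n * 60), n,
                             dimnames = list(NULL, paste0("n", 1:60))))
  ms <- detect_modules(expr, power = 6, min_size = 20)
  expect_gte(max(ms$assignments), 1)
  traits <- data.frame(BW = lat)
  hubs <- hub_genes(ms, expr, traits)
  expect_true("g1" %in% hubs$gene_id)
  expect_true(all(abs(hubs$best_trait_r) > 0.8))
  expect_true(all(hubs$kme > 0.2))
  # no gene correlated enough with any trait -> empty report
  hubs_none <- hub_genes(ms, expr, data.frame(BW = rnorm(n)))
  expect_equal(nrow(hubs_none), 0)
})
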