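test_that("informative SNPs follow the het/hom definitions exactly", {
  combos <- expand.grid(mother = 0:2, fetus = 0:2)
  ids <- sprintf("1:%d:A:G", seq_len(nrow(combos)))
  mother <- setNames(combos$mother, ids)
  fetus <- setNames(combos$fetus, ids)
  snps <- find_informative_snps(mother, fetus)
  # fetus het + mother hom -> fetal-specific
  expect_setequal(snps$fetal_specific$variant_id,
                  ids[combos$fetus == 1 & combos$mother != 1])
  # mother het + fetus hom -> maternal-specific
  expect_setequal(snps$maternal_specific$variant_id,
                  ids[combos$mother == 1 & combos$fetus != 1])
  # disjoint; het/het and hom/hom excluded
  expect_length(intersect(snps$fetal_specific$variant_id,
                          snps$maternal_specific$variant_id), 0)
  both_het <- ids[combos$mother == 1 & combos$fetus == 1]
  expect_false(any(both_het %in% c(snps$fetal_specific$variant_id,
                                   snps$maternal_specific$variant_id)))
  # the specific allele is the one the hom member lacks
  fs <- snps$fetal_specific
  expect_equal(fs$specific_allele[match(ids[combos$mother == 0 &
                                              combos$fetus == 1],
                                        fs$variant_id)], "alt")
  expect_equal(fs$specific_allele[match(ids[combos$mother == 2 &
                                              combos$fetus == 1],
                                        fs$variant_id)], "ref")
  expect_error(find_informative_snps(setNames(0L, "a"), setNames(0L, "b")),
               "no shared variants")
})

test_that("allelic ratio pools counts and handles degenerate input", {
  expect_equal(allelic_ratio(30, 10), 0.25)
  expect_equal(allelic_ratio(c(10, 20, 5), c(0, 0, 0)), 0)
  expect_true(is.na(allelic_ratio(c(0, 0), c(0, 0))))
  expect_error(allelic_ratio(numeric(0), numeric(0)), "empty")
  expect_error(allelic_ratio(c(1, -1), c(1, 1)), "negative")
  # equal per-SNP depth: pooled ratio == mean of per-SNP ratios
  for (seed in 1:20) {
    set.seed(seed)
    depth <- 40
    b <- rbinom(30, depth, runif(1))
    expect_equal(allelic_ratio(depth - b, b), mean(b / depth))
  }
})

test_that("origin estimates average replicates and enforce minimum SNPs", {
  pair <- make_informative_pair(n_fetal = 50, n_maternal = 50)
  snps <- find_informative_snps(pair$mother, pair$fetus)
  ac <- simulate_allelic_counts(pair$mother, pair$fetus, 0.6, depth = 100,
                                seed = 5)
  est <- estimate_origin(ac, snps, seed = 11)
  expect_equal(est$R_f, mean(est$replicate_R_f))
  expect_equal(est$R_m, mean(est$replicate_R_m))
  expect_length(est$replicate_R_f, 5)
  expect_true(est$fetal_fraction >= 0 && est$fetal_fraction <= 1)

  small <- make_informative_pair(n_fetal = 4, n_maternal = 50)
  snps4 <- find_informative_snps(small$mother, small$fetus)
  ac4 <- simulate_allelic_counts(small$mother, small$fetus, 0.6,
                                 depth = 100, seed = 6)
  expect_error(estimate_origin(ac4, snps4, min_snps = 5),
               class = "placentex_insufficient_snps")
})

test_that("fetal fraction is recovered across the mixing range", {
  pair <- make_informative_pair(n_fetal = 50, n_maternal = 50)
  snps <- find_informative_snps(pair$mother, pair$fetus)
  grid <- c(0, 0.3, 0.5, 1)
  est <- sapply(seq_along(grid), function(i) {
    ac <- simulate_allelic_counts(pair$mother, pair$fetus, grid[i],
                                  depth = 100, seed = 100 + i)
    estimate_origin(ac, snps, seed = 200 + i)$fetal_fraction
  })
  expect_true(all(abs(est - grid) <= 0.05))
})

test_that("R_f rises and R_m falls monotonically with the true fraction", {
  pair <- make_informative_pair(n_fetal = 50, n_maternal = 50)
  snps <- find_informative_snps(pair$mother, pair$fetus)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  rf <- rm <- numeric(length(grid))
  for (i in seq_along(grid)) {
    vals <- sapply(1:3, function(r) {
      ac <- simulate_allelic_counts(pair$mother, pair$fetus, grid[i],
                                    depth = 100, seed = 1000 + 10 * i + r)
      e <- estimate_origin(ac, snps, seed = 2000 + 10 * i + r)
      c(e$R_f, e$R_m)
    })
    rf[i] <- mean(vals[1, ])
    rm[i] <- mean(vals[2, ])
  }
  expect_true(all(diff(rf) > 0))
  expect_true(all(diff(rm) < 0))
})

test_that("cohort-level estimation records per-sample failures and continues", {
  cfg <- tiny_sim_config(seed = 9, n_genes = 50, n_snps = 300)
  co <- simulate_cohort(cfg, components = c("genotypes", "allelic"))
  sub <- co$metadata$sample_id[1:10]
  ac <- co$allelic_counts[co$allelic_counts$sample_id %in% sub[1:9], ]
  md <- co$metadata[co$metadata$sample_id %in% sub, ]
  res <- estimate_origin_cohort(ac, md, co$mother_gt, co$fetus_gt, seed = 4)
  expect_equal(nrow(res), 10)
  missing_row <- res[res$sample_id == sub[10], ]
  expect_true(is.na(missing_row$fetal_fraction))
  expect_match(missing_row$error, "no allelic counts")
  done <- res[!is.na(res$fetal_fraction), ]
  expect_true(all(abs(done$fetal_fraction -
                        co$truth$fetal_fraction[done$sample_id]) < 0.1))
})
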