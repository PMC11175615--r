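test_that("fetal genotypes are Mendelian-consistent with the mother", {
  for (seed in 1:3) {
    set.seed(seed)
    n_snp <- 500
    freqs <- runif(n_snp, 0.1, 0.9)
    mother <- matrix(rbinom(n_snp * 10, 2, rep(freqs, 10)), n_snp, 10)
    mother[1, 1] <- NA
    fetus <- simulate_fetus_genotypes(mother, freqs, seed = seed)
    # a fetus must carry at least one maternal allele: mother 0 forbids
    # fetus 2, mother 2 forbids fetus 0
    expect_false(any(mother == 0 & fetus == 2, na.rm = TRUE))
    expect_false(any(mother == 2 & fetus == 0, na.rm = TRUE))
    expect_true(all(fetus %in% 0:2 | is.na(fetus)))
    expect_true(is.na(fetus[1, 1]))
  }
})

test_that("transmission and paternal draws follow binomial expectations", {
  n <- 10000
  mother <- matrix(1L, n, 1)  # all heterozygous
  fetus <- simulate_fetus_genotypes(mother, rep(0.5, n), seed = 42)
  # dosage = transmitted (Bern 0.5) + paternal (Bern 0.5); mean 1,
  # var 0.5/n
  expect_lt(abs(mean(fetus) - 1), 3 * sqrt(0.5 / n))
  # near-zero paternal frequency isolates the transmitted allele
  fetus2 <- simulate_fetus_genotypes(mother, rep(1e-9, n), seed = 43)
  expect_lt(abs(mean(fetus2) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("allele-specific counts match the binomial mixture expectation", {
  n <- 2000
  mother <- setNames(rep(0L, n), sprintf("v%d", 1:n))  # fetal-specific SNPs
  fetus <- setNames(rep(1L, n), names(mother))
  frac_b <- function(ac) sum(ac$b_count) / sum(ac$a_count + ac$b_count)
  ac1 <- simulate_allelic_counts(mother, fetus, 1, depth = 100, seed = 1)
  expect_lt(abs(frac_b(ac1) - 0.5), 3 * sqrt(0.25 / (100 * n)))
  ac0 <- simulate_allelic_counts(mother, fetus, 0, depth = 100, seed = 2)
  expect_identical(sum(ac0$b_count), 0L)
  ac7 <- simulate_allelic_counts(mother, fetus, 0.7, depth = 100, seed = 3)
  expect_lt(abs(frac_b(ac7) - 0.35), 3 * sqrt(0.35 * 0.65 / (100 * n)))
  expect_error(simulate_allelic_counts(mother, fetus, 0.5, depth = 0),
               "depth")
})

test_that("count simulation is deterministic and recovers injected effects", {
  cfg <- sim_config(n_genes = 600, n_snps = 50,
                    module_sizes = c(50, 40, 30, 30),
                    deg_architecture = list(male = c(UC = 50), lfc_mean = 2,
                                            lfc_sd = 0, lfc_min = 2),
                    layers = "UC",
                    layer_fetal_fraction = c(UC = 1),
                    seed = 7)
  co1 <- simulate_cohort(cfg, components = "counts")
  co2 <- simulate_cohort(cfg, components = "counts")
  expect_identical(co1$counts, co2$counts)

  truth_deg <- co1$truth$deg$UC$male$gene_id
  expect_length(truth_deg, 50)
  cnt <- co1$counts$UC
  md <- co1$metadata[match(colnames(cnt), co1$metadata$sample_id), ]
  res <- run_de(cnt, md, stratum = "male")
  called <- res$gene_id[res$is_deg]
  expect_gte(length(intersect(called, truth_deg)), 0.8 * length(truth_deg))
  expect_lte(length(setdiff(called, truth_deg)), 5)
})

test_that("traits follow the module loadings", {
  lat <- matrix(rnorm(5000 * 2), 5000,
                dimnames = list(NULL, c("M1", "M2")))
  L0 <- matrix(0, 2, 2, dimnames = list(c("M1", "M2"), c("BW", "PLV")))
  tr0 <- simulate_traits(lat, L0, noise_sd = 1, seed = 1)
  expect_lt(max(abs(cor(tr0$BW, lat)), abs(cor(tr0$PLV, lat))),
            3 / sqrt(5000))
  L1 <- matrix(c(1, 0), 2, 1, dimnames = list(c("M1", "M2"), "BW"))
  tr1 <- simulate_traits(lat, L1, noise_sd = 0, seed = 2)
  expect_equal(cor(tr1$BW, lat[, "M1"]), 1)
  bad <- matrix(1, 2, 1, dimnames = list(c("M1", "M2"), "NOT_A_TRAIT"))
  expect_error(simulate_traits(lat, bad), "unknown trait")
})

test_that("the default cohort reproduces the study shape with closed truth", {
  cfg <- tiny_sim_config(seed = 3)
  co <- simulate_cohort(cfg, components = "counts")
  expect_equal(nrow(co$metadata), 69 * 7)
  expect_equal(nrow(co$pair_metadata), 69)
  expect_equal(as.vector(table(co$pair_metadata$population)[c("Tibetan", "Han")]),
               c(35, 34))
  sexes <- table(co$pair_metadata$population, co$pair_metadata$infant_sex)
  expect_equal(as.vector(sexes["Tibetan", c("male", "female")]), c(16, 19))
  expect_equal(as.vector(sexes["Han", c("male", "female")]), c(21, 13))
  # ground-truth closure: every truth id resolves against generated data
  genes <- rownames(co$counts$UC)
  all_deg <- unlist(lapply(co$truth$deg, function(l)
    c(l$male$gene_id, l$female$gene_id)))
  expect_true(all(all_deg %in% genes))
  expect_true(all(names(co$truth$module_assignment) %in% genes))
  expect_setequal(names(co$truth$fetal_fraction), co$metadata$sample_id)
  expect_equal(sum(co$truth$module_assignment > 0), sum(cfg$module_sizes))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(module_sizes = c(3000, 100)), "length n_modules")
  expect_error(sim_config(n_modules = 2, module_sizes = c(1500, 1000)),
               "exceeds n_genes")
  expect_error(sim_config(layer_fetal_fraction = c(UC = 1.2)[0]), "cover")
  expect_error(sim_config(sex_split = list(pop1 = c(male = 1, female = 1),
                                           pop2 = c(male = 21, female = 13))),
               "sex_split")
  expect_error(sim_config(seq_error = 1), "seq_error")
})
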