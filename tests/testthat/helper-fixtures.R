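# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# sample x gene matrix with 3 planted correlated blocks plus noise genes
make_block_expr <- function(seed, n = 37, block_size = 60, n_noise = 120,
                            n_blocks = 3, within_cor = 0.7,
                            graded = FALSE) {
  set.seed(seed)
  lat <- matrix(rnorm(n * n_blocks), n)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    w <- if (graded) runif(block_size, 0.4, 0.95)
         else rep(sqrt(within_cor), block_size)
    sapply(w, function(wi) wi * lat[, b] + sqrt(1 - wi^2) * rnorm(n))
  })
  expr <- cbind(do.call(cbind, blocks), matrix(rnorm(n * n_noise), n))
  colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  attr(expr, "truth") <- c(rep(seq_len(n_blocks), each = block_size),
                           rep(0L, n_noise))
  attr(expr, "latents") <- lat
  expr
}

# NB count matrix with two populations, optional injected log2FC on the
# first `n_de` genes (population "Tibetan" relative to "Han"); the
# injected signs alternate so normalization stays centred, and
# `true_lfc` records the signed truth
make_nb_counts <- function(seed, n_genes = 500, n1 = 16, n2 = 21,
                           lfc = 0, n_de = 0, libsize_sd = 0.2) {
  set.seed(seed)
  n <- n1 + n2
  md <- data.frame(
    population = rep(c("Tibetan", "Han"), c(n1, n2)),
    infant_sex = sample(c("male", "female"), n, replace = TRUE),
    maternal_age = sample(20:40, n, replace = TRUE),
    stringsAsFactors = FALSE)
  base <- rlnorm(n_genes, log(100), 1.2)
  disp <- rgamma(n_genes, 2, scale = 0.05)
  ls <- rlnorm(n, 0, libsize_sd)
  mu <- outer(base, ls)
  true_lfc <- numeric(n_genes)
  if (n_de > 0) {
    true_lfc[seq_len(n_de)] <- lfc * rep_len(c(1, -1), n_de)
    mu[seq_len(n_de), md$population == "Tibetan"] <-
      mu[seq_len(n_de), md$population == "Tibetan"] *
        2^true_lfc[seq_len(n_de)]
  }
  cnt <- matrix(rnbinom(n_genes * n, mu = mu, size = rep(1 / disp, n)),
                n_genes, n,
                dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                paste0("s", seq_len(n))))
  list(counts = cnt, metadata = md, n_de = n_de, true_lfc = true_lfc)
}

# one mother-fetus pair with the requested numbers of informative SNPs
make_informative_pair <- function(n_fetal = 50, n_maternal = 50,
                                  n_uninformative = 20) {
  n <- n_fetal + n_maternal + n_uninformative
  ids <- sprintf("1:%d:A:G", seq_len(n) * 100L)
  mother <- c(rep(0L, n_fetal), rep(1L, n_maternal),
              rep(1L, n_uninformative))
  fetus <- c(rep(1L, n_fetal), rep(0L, n_maternal),
             rep(1L, n_uninformative))
  names(mother) <- names(fetus) <- ids
  list(mother = mother, fetus = fetus,
       fetal_ids = ids[seq_len(n_fetal)],
       maternal_ids = ids[n_fetal + seq_len(n_maternal)])
}

# small scaled-down sim_config used by pipeline-level tests
tiny_sim_config <- function(seed = 1L, n_genes = 250, n_snps = 200) {
  sizes <- pmax(5, round(n_genes * c(0.2, 0.16, 0.12, 0.12)))
  sim_config(n_genes = n_genes, n_snps = n_snps,
             module_sizes = sizes, seed = seed)
}

# independent step-up BH implementation used as an oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
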