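test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_strains = 6L, group_labels = c(white = 3L, gray = 3L),
                    n_chroms = 2L, n_clusters_per_chrom = 5L, seed = 141L)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$hap1, b$truth$hap1)
  expect_error(sim_config(n_strains = 4L, group_labels = c(white = 2L, gray = 2L),
                          seed = NULL), "seed")
})

test_that("clone strains carry identical genotype vectors and GS 100", {
  cfg <- sim_config(n_strains = 6L, group_labels = c(white = 3L, gray = 3L),
                    n_chroms = 2L, n_clusters_per_chrom = 8L,
                    clone_pairs = list(c("S06", "S01")), seed = 151L)
  sim <- simulate_population(cfg)
  expect_equal(sim$truth$hap1[, "S06"], sim$truth$hap1[, "S01"])
  expect_equal(sim$table$gt[, 6], sim$table$gt[, 1])
  mk <- select_markers(scan_windows(polymorphic_screen(sim$table)))
  mt <- derive_marker_truth(sim$truth, mk)
  cts <- simulate_counts(mt, depth = 60, error_rate = 0, seed = 152L)
  r <- compute_gs(genotype_strain(cts$S01, mk), genotype_strain(cts$S06, mk))
  expect_equal(r$gs, 100)
  expect_equal(classify_pair(r$gs), "identical")
})

test_that("poisson layout reproduces genome-scale SNP counts", {
  # a scaled-down genome: 3 chromosomes of 300 kb at 1 SNP / 104 bp
  cfg <- sim_config(n_strains = 4L, group_labels = c(white = 2L, gray = 2L),
                    n_chroms = 3L, layout = "poisson",
                    chrom_length_bp = 3e5, snp_density = 1 / 104, seed = 161L)
  sim <- simulate_population(cfg)
  lambda <- 3 * 3e5 / 104
  expect_lt(abs(n_sites(sim$table) - lambda), 3 * sqrt(lambda))
  # too-sparse genomes cannot host a 2-SNP window
  cfg2 <- sim_config(n_strains = 4L, group_labels = c(white = 2L, gray = 2L),
                     n_chroms = 1L, layout = "poisson",
                     chrom_length_bp = 1e6, snp_density = 5e-6, seed = 162L)
  expect_error(simulate_population(cfg2), "density|window")
})

test_that("hybrid offspring draw one cluster haplotype from each parent", {
  cfg <- sim_config(n_strains = 6L, group_labels = c(white = 3L, gray = 3L),
                    n_chroms = 3L, n_clusters_per_chrom = 20L,
                    hybrid_trios = list(list(parents = c("S01", "S02"),
                                             children = c("S05", "S06"))),
                    het_rate = 1, seed = 171L)
  sim <- simulate_population(cfg)
  tr <- sim$truth
  cl <- tr$map$cluster
  for (child in c("S05", "S06")) {
    for (cid in unique(cl)) {
      rows <- which(cl == cid)
      from_a <- identical(tr$hap1[rows, child], tr$hap1[rows, "S01"]) ||
        identical(tr$hap1[rows, child], tr$hap2[rows, "S01"])
      from_b <- identical(tr$hap2[rows, child], tr$hap1[rows, "S02"]) ||
        identical(tr$hap2[rows, child], tr$hap2[rows, "S02"])
      expect_true(from_a && from_b)
    }
  }
  # identical homozygous parents beget identical offspring
  cfg2 <- sim_config(n_strains = 4L, group_labels = c(white = 2L, gray = 2L),
                     n_chroms = 1L, n_clusters_per_chrom = 10L,
                     het_rate = 0,
                     clone_pairs = list(c("S02", "S01")),
                     seed = 172L)
  sim2 <- simulate_population(cfg2)
  h <- simulate_hybrid(sim2$truth, "S01", "S02", seed = 173L)
  expect_equal(h$hap1, unname(sim2$truth$hap1[, "S01"]))
  # two seeds give different siblings
  hx <- simulate_hybrid(sim$truth, "S01", "S02", seed = 174L)
  hy <- simulate_hybrid(sim$truth, "S01", "S02", seed = 175L)
  expect_false(identical(hx, hy))
})

test_that("sibling marker sharing matches the Mendelian expectation", {
  # 1000 two-SNP clusters; parent A carries cluster haplotypes {00, 11},
  # parent B {01, 10} - four distinguishable words, so two siblings share a
  # cluster genotype iff they drew the same haplotype from each parent: 1/4
  n_cl <- 1000L
  map <- data.frame(chrom = "chr01",
                    pos = as.integer(rbind(seq(1, by = 200L, length.out = n_cl),
                                           seq(2, by = 200L, length.out = n_cl))),
                    cluster = rep(paste0("c", seq_len(n_cl)), each = 2L))
  hapA1 <- rep(c(0L, 0L), n_cl); hapA2 <- rep(c(1L, 1L), n_cl)
  hapB1 <- rep(c(0L, 1L), n_cl); hapB2 <- rep(c(1L, 0L), n_cl)
  truth <- structure(list(
    strains = c("PA", "PB"), groups = c(PA = "g", PB = "g"), map = map,
    ref = rep("A", 2L * n_cl), alt = rep("T", 2L * n_cl),
    hap1 = cbind(PA = hapA1, PB = hapB1), hap2 = cbind(PA = hapA2, PB = hapB2),
    pedigree = list(), clones = character(0),
    cfg = list(depth = 60)
  ), class = "sim_truth")
  s1 <- simulate_hybrid(truth, "PA", "PB", seed = 181L)
  s2 <- simulate_hybrid(truth, "PA", "PB", seed = 182L)
  geno <- function(h) {
    m1 <- matrix(h$hap1, nrow = 2L); m2 <- matrix(h$hap2, nrow = 2L)
    paste(pmin(m1[1, ], m2[1, ]), pmax(m1[1, ], m2[1, ]),
          pmin(m1[2, ], m2[2, ]), pmax(m1[2, ], m2[2, ]))
  }
  share <- mean(geno(s1) == geno(s2))
  expect_lt(abs(share - 0.25), 4 * sqrt(0.25 * 0.75 / n_cl))
})

test_that("simulated counts follow the read model", {
  mk <- toy_markers(c("m1", "m2"))
  mt <- structure(list(
    marker_ids = c("m1", "m2"), strains = "S01",
    h1 = matrix(c("AAA", "CCC"), 2, 1, dimnames = list(c("m1", "m2"), "S01")),
    h2 = matrix(c("AAA", "GGG"), 2, 1, dimnames = list(c("m1", "m2"), "S01"))
  ), class = "marker_truth")
  cts <- simulate_counts(mt, depth = 100, error_rate = 0, seed = 191L)$S01
  # hom marker: a single haplotype gets all reads
  expect_equal(names(cts$entries$m1), "AAA")
  # het marker: two haplotypes at roughly 50/50
  expect_setequal(names(cts$entries$m2), c("CCC", "GGG"))
  frac <- cts$entries$m2[["CCC"]] / sum(cts$entries$m2)
  expect_lt(abs(frac - 0.5), 0.2)
  # error rate: off-haplotype read fraction ~ 1 - (1-e)^3 for 3-SNP windows
  set.seed(192)
  e <- 0.01
  mt_hom <- structure(list(
    marker_ids = sprintf("m%03d", 1:300), strains = "S01",
    h1 = matrix("ACG", 300, 1, dimnames = list(sprintf("m%03d", 1:300), "S01")),
    h2 = matrix("ACG", 300, 1, dimnames = list(sprintf("m%03d", 1:300), "S01"))
  ), class = "marker_truth")
  cts2 <- simulate_counts(mt_hom, depth = 60, error_rate = e, seed = 193L)$S01
  tot <- sum(vapply(cts2$entries, sum, numeric(1L)))
  off <- sum(vapply(cts2$entries, function(c_) {
    sum(c_[setdiff(names(c_), "ACG")])
  }, numeric(1L)))
  p_off <- 1 - (1 - e)^3
  expect_lt(abs(off / tot - p_off), 4 * sqrt(p_off * (1 - p_off) / tot))
})

test_that("engineered sharing produces the exact requested agreement count", {
  cfg <- sim_config(n_strains = 4L, group_labels = c(white = 2L, gray = 2L),
                    n_chroms = 2L, n_clusters_per_chrom = 10L, seed = 201L)
  sim <- simulate_population(cfg)
  mk <- select_markers(scan_windows(polymorphic_screen(sim$table)))
  mt <- derive_marker_truth(sim$truth, mk)
  for (f in c(0.25, 1.0)) {
    mt2 <- apply_sharing_targets(mt, list(list(a = "S01", b = "S03", f = f)),
                                 seed = 202L)
    agree <- vapply(seq_along(mt2$marker_ids), function(i) {
      mnpkit:::truth_genotype(mt2, i, "S01") ==
        mnpkit:::truth_genotype(mt2, i, "S03")
    }, logical(1L))
    expect_equal(sum(agree), round(f * length(mt2$marker_ids)))
  }
})
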