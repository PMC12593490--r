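test_that("GS reproduces the published worked examples over 369 markers", {
  # printed value <- inverted integer match count
  cases <- list(c(10, 2.71), c(44, 11.92), c(100, 27.10), c(168, 45.53),
                c(203, 55.01), c(255, 69.11), c(275, 74.53), c(327, 88.62))
  for (cs in cases) {
    p <- profiles_with_overlap(369L, cs[1])
    r <- compute_gs(p$a, p$b)
    expect_equal(r$n, as.integer(cs[1]))
    expect_equal(r$N, 369L)
    expect_equal(r$gs, cs[2])
  }
  ident <- profiles_with_overlap(369L, 369L)
  expect_equal(compute_gs(ident$a, ident$b)$gs, 100)
  none <- profiles_with_overlap(369L, 0L)
  expect_equal(compute_gs(none$a, none$b)$gs, 0)
})

test_that("rounding is half-away-from-zero at two decimals", {
  # 255/369 = 69.1056...; 0.5-ulp cases distinguish from round-half-even
  expect_equal(mnpkit:::round_half_up(69.105, 2), 69.11)
  expect_equal(mnpkit:::round_half_up(69.104999, 2), 69.10)
  expect_equal(mnpkit:::round_half_up(2.715, 2), 2.72)
})

test_that("heterozygote matching is exact set equality; MISSING handling by mode", {
  gcall <- function(haps) {
    structure(list(haplotypes = sort(haps),
                   support = structure(rep(25L, length(haps)), names = sort(haps)),
                   total_reads = 50L, missing = FALSE), class = "mnp_genotype")
  }
  gmiss <- structure(list(haplotypes = NULL, support = integer(0),
                          total_reads = 0L, missing = TRUE),
                     class = "mnp_genotype")
  a <- mnp_profile("a", list(m1 = gcall(c("AA", "TT")), m2 = gcall("CC"),
                             m3 = gcall("GG")))
  b <- mnp_profile("b", list(m1 = gcall(c("AA", "TT")), m2 = gcall(c("AA", "CC")),
                             m3 = gmiss))
  # m1 matches (same pair), m2 partial overlap is a non-match, m3 missing
  tot <- compute_gs(a, b, mode = "total")
  expect_equal(tot$n, 1L)
  expect_equal(tot$N, 3L)
  shr <- compute_gs(a, b, mode = "shared")
  expect_equal(shr$n, 1L)
  expect_equal(shr$N, 2L)
  # self-similarity is 100 in shared mode even with a missing call
  a2 <- mnp_profile("a2", list(m1 = gcall("AA"), m2 = gmiss, m3 = gcall("GG")))
  expect_equal(compute_gs(a2, a2, mode = "shared")$gs, 100)
  # disjoint universes are a contract error
  c_ <- mnp_profile("c", list(z1 = gcall("AA")))
  expect_error(compute_gs(a, c_), "universe")
})

test_that("GS is symmetric and the matrix mirrors it with a 100 diagonal", {
  set.seed(61)
  ids <- sprintf("m%03d", 1:40)
  mk <- toy_markers(ids)
  profs <- lapply(sprintf("s%d", 1:5), function(s) {
    calls <- lapply(ids, function(m) {
      hap <- paste(sample(c("A", "T"), 2, replace = TRUE), collapse = "")
      call_genotype(structure(50L, names = hap))
    })
    names(calls) <- ids
    mnp_profile(s, calls)
  })
  for (i in 1:4) {
    for (j in (i + 1):5) {
      ab <- compute_gs(profs[[i]], profs[[j]])
      ba <- compute_gs(profs[[j]], profs[[i]])
      expect_equal(ab$gs, ba$gs)
      expect_equal(ab$n, ba$n)
    }
  }
  db <- build_database(mk, profs)
  m <- gs_matrix(db)
  expect_equal(m$gs, t(m$gs))
  expect_equal(unname(diag(m$gs)), rep(100, 5))
  expect_equal(sum(upper.tri(m$gs)), choose(5, 2))
  expect_error(gs_matrix(build_database(mk, profs[1])), "2 strains")
})

test_that("identity classification is inclusive at 99%", {
  expect_equal(classify_pair(99.00), "identical")
  expect_equal(classify_pair(98.99), "distinct")
  expect_equal(classify_pair(88.62), "distinct")
  expect_equal(classify_pair(100), "identical")
  expect_error(classify_pair(101), "contract")
})

test_that("clustering separates engineered groups and honours linkage choice", {
  gcall <- function(hap) call_genotype(structure(50L, names = hap))
  ids <- sprintf("m%02d", 1:10)
  mk <- toy_markers(ids)
  mkprof <- function(s, hap) {
    calls <- lapply(ids, function(m) gcall(hap))
    names(calls) <- ids
    mnp_profile(s, calls)
  }
  profs <- c(lapply(c("a1", "a2", "a3"), mkprof, hap = "AA"),
             lapply(c("b1", "b2"), mkprof, hap = "TT"))
  m <- gs_matrix(build_database(mk, profs))
  cl <- cluster_gs(m)
  groups <- stats::cutree(cl$hclust, k = 2)
  expect_length(unique(groups[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(groups[c("b1", "b2")]), 1L)
  expect_false(groups[["a1"]] == groups[["b1"]])
  expect_s3_class(cl$phylo, "phylo")

  # single vs average linkage on a hand-built 4x4 similarity matrix:
  # d(a,b)=0.1, d(c,d)=0.1, cross distances 0.5 except d(b,c)=0.2.
  gs <- matrix(100 * (1 - 0.5), 4, 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  gs["a", "b"] <- gs["b", "a"] <- 90
  gs["c", "d"] <- gs["d", "c"] <- 90
  gs["b", "c"] <- gs["c", "b"] <- 80
  diag(gs) <- 100
  m2 <- structure(list(strains = rownames(gs), gs = gs,
                       n = gs, N = gs, mode = "total"), class = "gs_matrix")
  avg <- cluster_gs(m2, "average")
  sng <- cluster_gs(m2, "single")
  # both first merge the 0.1 pairs; the final merge height differs:
  # single -> min cross distance 0.2; average -> mean(0.5,0.2,0.5,0.5) = 0.425
  expect_equal(sort(avg$hclust$height), c(0.1, 0.1, 0.425))
  expect_equal(sort(sng$hclust$height), c(0.1, 0.1, 0.2))
})

test_that("group range summaries report min/max/mean per label pair", {
  gcall <- function(hap) call_genotype(structure(50L, names = hap))
  ids <- sprintf("m%04d", 1:369)
  mk <- toy_markers(ids)
  mkprof <- function(s, idx_aa) {
    calls <- lapply(seq_along(ids), function(i) {
      gcall(if (i %in% idx_aa) "AA" else paste0("TT", s))
    })
    names(calls) <- ids
    mnp_profile(s, calls)
  }
  # sibling trio with pairwise matches |h1&h2| = 275, |h1&h3| = 203,
  # |h2&h3| = 168 -> GS 74.53 / 55.01 / 45.53 over 369 markers
  p1 <- mkprof("h1", 1:310)
  p2 <- mkprof("h2", c(1:275, 331:350))
  p3 <- mkprof("h3", c(1:168, 276:310, 351:369))
  m <- gs_matrix(build_database(mk, list(p1, p2, p3)))
  groups <- c(h1 = "gray", h2 = "gray", h3 = "gray")
  sm <- summarize_ranges(m, groups)
  expect_equal(sm$min, 45.53)
  expect_equal(sm$max, 74.53)
  expect_equal(sm$mean, mnpkit:::round_half_up((74.53 + 55.01 + 45.53) / 3, 2))
  expect_equal(sm$n_pairs, 3L)
  # identical strains: min = max = mean = 100
  q <- lapply(c("x1", "x2"), mkprof, idx_aa = 1:369)
  mq <- gs_matrix(build_database(mk, q))
  smq <- summarize_ranges(mq, c(x1 = "white", x2 = "white"))
  expect_equal(c(smq$min, smq$max, smq$mean), c(100, 100, 100))
  expect_error(summarize_ranges(mq, c(x1 = "white", zz = "white")),
               "unknown|labelled")
})

test_that("engineered sharing fraction is recovered as GS = 100f", {
  cfg <- sim_config(n_strains = 6L, group_labels = c(white = 3L, gray = 3L),
                    n_chroms = 3L, n_clusters_per_chrom = 10L, seed = 71L)
  sim <- simulate_population(cfg)
  mk <- select_markers(scan_windows(polymorphic_screen(sim$table)))
  mt <- derive_marker_truth(sim$truth, mk)
  mt <- apply_sharing_targets(mt, list(list(a = "S01", b = "S02", f = 0.5)),
                              seed = 72L)
  cts <- simulate_counts(mt, depth = 60, error_rate = 0, seed = 73L)
  pa <- genotype_strain(cts$S01, mk)
  pb <- genotype_strain(cts$S02, mk)
  r <- compute_gs(pa, pb)
  eng <- attr(mt, "engineered")[["S01:S02"]]
  expect_equal(r$n, eng$n_shared)
  expect_equal(r$gs, mnpkit:::round_half_up(100 * eng$n_shared / eng$N, 2))
})
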