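test_that("BH adjustment matches hand computation and the stats oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))
    q <- fdr_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p))
  }
})

test_that("classification follows the five-category rules", {
  expect_equal(classify_taxon(0.8, 0.0, 0.01), "US_A")
  expect_equal(classify_taxon(0.0, 0.8, 0.01), "US_B")
  expect_equal(classify_taxon(0.6, 0.2, 0.01), "ES_A")
  expect_equal(classify_taxon(0.2, 0.6, 0.01), "ES_B")
  expect_equal(classify_taxon(0.6, 0.2, 0.20), "indifferent")
  expect_equal(classify_taxon(0.0, 0.0, 0.01), "indifferent")
  expect_equal(classify_taxon(0.3, 0.3, 0.01), "indifferent")
  expect_equal(classify_taxon(c(0.8, 0.2), c(0, 0.6), c(0.01, 0.01)),
               c("US_A", "ES_B"))
})

test_that("sp_test is seed-deterministic and swaps cleanly under relabeling", {
  set.seed(3)
  g <- generate_planted(n_taxa = 40, n_unique = 5, n_enriched = 5, seed = 21,
                        samples_per_habitat = 6)
  parts <- partition_by_habitat(g$table, g$map)
  r1 <- sp_test(parts$A, parts$B, n_perm = 200, seed = 5)
  r2 <- sp_test(parts$A, parts$B, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  r3 <- sp_test(parts$A, parts$B, n_perm = 200, seed = 6)
  expect_false(identical(r1$pseudo_p, r3$pseudo_p))
  # equal group sizes: swapping the treatments swaps categories exactly
  swapped <- sp_test(parts$B, parts$A, n_perm = 200, seed = 5)
  expect_equal(swapped$pseudo_p, r1$pseudo_p)
  expect_equal(swapped$delta_A, r1$delta_B)
  map_swap <- c(US_A = "US_B", US_B = "US_A", ES_A = "ES_B", ES_B = "ES_A",
                indifferent = "indifferent")
  expect_equal(unname(map_swap[r1$category]), swapped$category)
})

test_that("degenerate pair of identical single samples yields all-indifferent", {
  v <- matrix(c(0.4, 0.6), 2, 1, dimnames = list(c("t1", "t2"), "sA"))
  w <- v
  colnames(w) <- "sB"
  r <- sp_test(abundance_table(v), abundance_table(w), n_perm = 50, seed = 1)
  # identical samples: both specificity lists coincide, so every taxon is
  # indifferent; under the strict exceedance rule the all-tied permutation
  # distribution gives T = 0 (see the mid-p option for a calibrated p)
  expect_true(all(r$category == "indifferent"))
  expect_true(all(r$obs_diff == 0))
  expect_true(all(r$T == 0))
  r_mid <- sp_test(abundance_table(v), abundance_table(w), n_perm = 50,
                   seed = 1, midp = TRUE)
  expect_true(all(r_mid$pseudo_p == 0.5))
})

test_that("taxa absent from both sides are dropped and reported", {
  v <- rbind(present = c(1, 2, 3, 4), ghost = c(0, 0, 0, 0))
  colnames(v) <- paste0("s", 1:4)
  a <- abundance_table(v[, 1:2])
  b <- abundance_table(v[, 3:4])
  r <- sp_test(a, b, n_perm = 20, seed = 1)
  expect_identical(attr(r, "dropped"), "ghost")
  expect_identical(r$taxon, "present")
})

test_that("sampled exceedance matches exhaustive enumeration at m = n = 2", {
  set.seed(8)
  v <- matrix(stats::rexp(5 * 4) * stats::rbinom(20, 1, 0.8), 5, 4,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  v <- sweep(v, 2, pmax(colSums(v), 1), "/")
  in_A <- c(TRUE, TRUE, FALSE, FALSE)
  truth <- oracle_sp_exceedance(v, in_A)
  r <- sp_test(abundance_table(v[, 1:2]), abundance_table(v[, 3:4]),
               n_perm = 4000, seed = 9)
  keep <- match(r$taxon, rownames(v))
  # Monte-Carlo error: 4000 draws from 6 equiprobable splits
  expect_true(all(abs(r$pseudo_p - truth[keep]) <
                    3 * sqrt(0.25 / 4000) + 0.02))
})

test_that("mid-p pseudo-p is calibrated on null data", {
  rej <- 0L
  n_tot <- 0L
  for (r in 1:20) {
    g <- generate_null(100, c("A", "B"), 10, seed = 500 + r)
    parts <- partition_by_habitat(g$table, g$map)
    sp <- sp_test(parts$A, parts$B, n_perm = 400, seed = 700 + r,
                  midp = TRUE)
    rej <- rej + sum(sp$pseudo_p <= 0.05)
    n_tot <- n_tot + nrow(sp)
  }
  expect_gte(rej, stats::qbinom(0.005, n_tot, 0.05))
  expect_lte(rej, stats::qbinom(0.995, n_tot, 0.05))
})

test_that("sdp_test respects fixed membership, q = 0 trivialities, empty categories", {
  g <- generate_planted(n_taxa = 60, n_unique = 10, n_enriched = 10,
                        fold = 8, seed = 31)
  parts <- partition_by_habitat(g$table, g$map)
  sp <- sp_test(parts$A, parts$B, n_perm = 300, seed = 13)
  sdp <- sdp_test(parts$A, parts$B, sp, n_perm = 300, seed = 13)
  expect_setequal(unique(sdp$category),
                  c("US_A", "US_B", "ES_A", "ES_B", "significant", "all"))
  us_a0 <- sdp[sdp$category == "US_A" & sdp$q == 0, ]
  if (us_a0$applicable) {
    expect_equal(us_a0$sd_B, 0)                   # absent side has richness 0
    expect_equal(us_a0$sd_A, sum(sp$category == "US_A"))
    expect_true(us_a0$trivial)
  }
  es_a0 <- sdp[sdp$category == "ES_A" & sdp$q == 0, ]
  if (es_a0$applicable) expect_equal(es_a0$sd_A, es_a0$sd_B)
  # determinism
  sdp2 <- sdp_test(parts$A, parts$B, sp, n_perm = 300, seed = 13)
  expect_identical(sdp, sdp2)
  # empty categories are marked not-applicable
  null_g <- generate_null(30, c("A", "B"), 4, seed = 77)
  np <- partition_by_habitat(null_g$table, null_g$map)
  nsp <- sp_test(np$A, np$B, n_perm = 100, seed = 3)
  nsdp <- sdp_test(np$A, np$B, nsp, n_perm = 100, seed = 3)
  empty <- nsdp[!nsdp$applicable, ]
  expect_true(all(is.na(empty$pseudo_p)))
  expect_true(all(nsdp$pseudo_p[nsdp$applicable] >= 0 &
                    nsdp$pseudo_p[nsdp$applicable] <= 1))
})

test_that("exclusively unique species is a disjoint XOR catalogue", {
  v <- rbind(only_h1  = c(1, 1, 0, 0, 0, 0),
             only_h2  = c(0, 0, 3, 0, 0, 0),
             shared   = c(1, 0, 1, 0, 0, 0),
             only_h3  = c(0, 0, 0, 0, 2, 2),
             nowhere  = c(0, 0, 0, 0, 0, 0),
             everywhere = c(1, 1, 1, 1, 1, 1))
  colnames(v) <- paste0("s", 1:6)
  map <- habitat_map(stats::setNames(rep(c("h1", "h2", "h3"), each = 2),
                                     colnames(v)), level = "class")
  cat_ <- exclusively_unique_species(abundance_table(v), map)
  expect_equal(cat_$h1, "only_h1")
  expect_equal(cat_$h2, "only_h2")
  expect_equal(cat_$h3, "only_h3")
  all_listed <- unlist(unclass(cat_))
  expect_false(anyDuplicated(all_listed) > 0)
  expect_false(any(c("shared", "nowhere", "everywhere") %in% all_listed))
})

test_that("volcano table carries the reference line and sentinels", {
  g <- generate_planted(n_taxa = 40, n_unique = 6, n_enriched = 6,
                        seed = 51)
  parts <- partition_by_habitat(g$table, g$map)
  sp <- sp_test(parts$A, parts$B, n_perm = 200, seed = 15)
  vol <- volcano_table(sp)
  expect_equal(attr(vol, "ref_line"), -log10(0.05), tolerance = 1e-12)
  expect_equal(round(attr(vol, "ref_line"), 3), 1.301)
  us_a <- vol$fc_class[sp$category == "US_A"]
  expect_true(all(us_a == "plus_inf"))
  expect_true(all(is.na(vol$log10_fc[vol$fc_class != "finite"])))
  eq <- sp$delta_A == sp$delta_B & sp$delta_A > 0
  if (any(eq)) expect_true(all(vol$log10_fc[eq] == 0))
})
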