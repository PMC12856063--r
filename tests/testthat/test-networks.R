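# Small specificity_matrix built directly from a delta matrix.
fake_spec <- function(delta) {
  structure(list(delta = delta,
                 A = (delta > 0) * 1, B = delta,
                 zero_total = character(), level = "class"),
            class = "specificity_matrix")
}

test_that("occurrence filtering uses ceiling for fractions and counts directly", {
  set.seed(2)
  delta <- matrix(0, 4, 318,
                  dimnames = list(paste0("t", 1:4), paste0("h", 1:318)))
  delta[1, 1:16] <- 0.5    # exactly at ceiling(0.05 * 318) = 16
  delta[2, 1:15] <- 0.5    # one short
  delta[3, ] <- 0.1        # everywhere
  f <- filter_by_occurrence(fake_spec(delta), min_fraction = 0.05)
  expect_setequal(rownames(f$delta), c("t1", "t3"))

  d10 <- matrix(0, 3, 10, dimnames = list(paste0("t", 1:3), paste0("h", 1:10)))
  d10[1, 1:6] <- 1
  d10[2, 1:5] <- 1
  d10[3, ] <- 1
  f10 <- filter_by_occurrence(fake_spec(d10), min_count = 6)
  expect_setequal(rownames(f10$delta), c("t1", "t3"))
  expect_warning(filter_by_occurrence(fake_spec(d10), min_count = 10),
                 NA)  # t3 everywhere is always kept
  expect_error(filter_by_occurrence(fake_spec(d10), min_count = 6,
                                    min_fraction = 0.5), "exactly one")
})

test_that("perfectly concordant and discordant taxa give signed unit edges", {
  delta <- rbind(up1 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                 up2 = c(0.15, 0.25, 0.33, 0.47, 0.52, 0.68),
                 down = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  colnames(delta) <- paste0("h", 1:6)
  net <- build_network(fake_spec(delta), mode = "taxon", alpha = 0.05)
  e <- net$edges
  key <- paste(e$u, e$v)
  expect_true("up1 up2" %in% key)
  expect_equal(e$rho[key == "up1 up2"], 1)
  expect_equal(e$sign[key == "up1 down"], -1L)
  expect_equal(e$rho[key == "up1 down"], -1)
})

test_that("edge list equals a brute-force pairwise oracle with BH", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(8:15, 1)
    H <- sample(10:14, 1)
    delta <- matrix(stats::runif(n * H) * stats::rbinom(n * H, 1, 0.8), n, H,
                    dimnames = list(paste0("t", 1:n), paste0("h", 1:H)))
    net <- build_network(fake_spec(delta), mode = "taxon", alpha = 0.05)
    # oracle: stats::cor.test per pair (t approximation), then BH
    pairs <- utils::combn(n, 2)
    oracle <- data.frame(t(apply(pairs, 2, function(ix) {
      ct <- suppressWarnings(
        stats::cor.test(delta[ix[1], ], delta[ix[2], ], method = "spearman",
                        exact = FALSE))
      c(rho = unname(ct$estimate), p = ct$p.value)
    })))
    oracle$q <- stats::p.adjust(oracle$p, "BH")
    keep <- which(oracle$q <= 0.05)
    expect_equal(nrow(net$edges), length(keep))
    if (length(keep)) {
      expect_equal(net$edges$u, rownames(delta)[pairs[1, keep]])
      expect_equal(net$edges$v, rownames(delta)[pairs[2, keep]])
      expect_equal(net$edges$rho, oracle$rho[keep], tolerance = 1e-10)
      expect_equal(net$edges$p, oracle$p[keep], tolerance = 1e-10)
    }
  }
})

test_that("habitat mode correlates columns, raising alpha only adds edges", {
  set.seed(44)
  delta <- matrix(stats::runif(20 * 6), 20, 6,
                  dimnames = list(paste0("t", 1:20), paste0("h", 1:6)))
  delta[, 2] <- delta[, 1] + stats::runif(20, 0, 0.01)  # near-duplicate class
  net <- build_network(fake_spec(delta), mode = "habitat", alpha = 0.05)
  expect_setequal(net$nodes, paste0("h", 1:6))
  strict <- build_network(fake_spec(delta), mode = "habitat", alpha = 0.01)
  loose <- build_network(fake_spec(delta), mode = "habitat", alpha = 0.10)
  strict_keys <- paste(strict$edges$u, strict$edges$v)
  loose_keys <- paste(loose$edges$u, loose$edges$v)
  expect_true(all(strict_keys %in% loose_keys))
})

test_that("constant rows are skipped with a report", {
  delta <- rbind(flat = rep(0.3, 5),
                 var1 = c(0.1, 0.2, 0.3, 0.4, 0.5),
                 var2 = c(0.5, 0.4, 0.3, 0.2, 0.1))
  colnames(delta) <- paste0("h", 1:5)
  expect_message(net <- build_network(fake_spec(delta), mode = "taxon"),
                 "flat")
  expect_identical(attr(net, "skipped"), "flat")
  expect_false("flat" %in% c(net$edges$u, net$edges$v))
})

test_that("PN ratio covers positive, zero and sentinel cases", {
  base <- list(nodes = c("a", "b"), mode = "taxon_over_habitats",
               alpha = 0.05, degree = c(a = 0L, b = 0L))
  mk <- function(signs) {
    net <- base
    net$edges <- data.frame(u = rep("a", length(signs)),
                            v = rep("b", length(signs)),
                            rho = signs * 0.9,
                            p = rep(0.001, length(signs)),
                            q_value = rep(0.001, length(signs)),
                            sign = as.integer(signs))
    structure(net, class = "ssd_network")
  }
  expect_equal(pn_ratio(mk(c(1, 1, 1, 1, 1, -1, -1))), 2.5)
  expect_identical(pn_ratio(mk(c(1, 1))), Inf)
  expect_equal(pn_ratio(mk(c(-1, -1, -1))), 0)
  expect_true(is.na(pn_ratio(mk(integer(0)))))
})

test_that("exports write TSV and GraphML", {
  skip_if_not_installed("igraph")
  delta <- rbind(a = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                 b = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7))
  colnames(delta) <- paste0("h", 1:6)
  net <- build_network(fake_spec(delta), mode = "taxon")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  expect_named(read.delim(tsv), c("u", "v", "rho", "p", "q_value", "sign"))
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), c("a", "b"))
})
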