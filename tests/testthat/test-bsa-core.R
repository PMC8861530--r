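test_that("pool index is alt/(ref+alt), undefined at depth 0, scale-free", {
  expect_equal(pool_index(10, 0), 0)
  expect_equal(pool_index(0, 12), 1)
  expect_equal(pool_index(20, 25), 25 / 45)
  expect_true(is.na(pool_index(0, 0)))
  expect_error(pool_index(-1, 5), "non-negative")
  # scale-free: multiplying both depths by k leaves the index unchanged
  set.seed(12)
  r <- sample(0:50, 20, replace = TRUE)
  a <- sample(1:50, 20, replace = TRUE)
  for (k in c(2, 7, 100)) {
    expect_equal(pool_index(k * r, k * a), pool_index(r, a))
  }
})

test_that("filter cascade implements both-pool low index and per-pool depth", {
  rec <- data.frame(
    ref_depth_S = c(32, 32, 1, 0, 30),
    alt_depth_S = c(8, 8, 5, 0, 10),
    ref_depth_T = c(32, 4, 25, 20, 20),
    alt_depth_T = c(8, 36, 25, 20, 20)
  )
  rec <- bsascreen:::compute_index(rec)
  rec <- apply_filters(rec, min_depth = 7, low_index = 0.3)
  # both pools at 0.2 -> fails; one pool at 0.9 rescues; depth 6 fails;
  # depth 0 (undefined index) fails; clean site passes
  expect_equal(rec$passed_filters, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # both-pool depth rule keeps the 6/50 site
  rec2 <- apply_filters(rec, min_depth = 7, depth_rule = "both")
  expect_true(rec2$passed_filters[3])
})

test_that("delta index is tolerant minus sensitive and bounded", {
  expect_equal(delta_index(0.5, 0.5), 0)
  expect_equal(delta_index(1, 0), -1)
  expect_true(is.na(delta_index(NA_real_, 0.5)))
  expect_true(all(abs(validated_deltas) >= 0.69 & abs(validated_deltas) <= 1))
})

test_that("null envelope widens with level, narrows with depth, and is seeded", {
  expect_error(null_delta_envelope(45, 45, 20, level = 1.2), "level")
  expect_error(null_delta_envelope(0, 45, 20), "depth")
  e95 <- null_delta_envelope(45, 45, 20, level = 0.95, seed = 1)
  e99 <- null_delta_envelope(45, 45, 20, level = 0.9999, seed = 1)
  expect_lt(e99["lo"], e95["lo"])
  expect_gt(e99["hi"], e95["hi"])
  expect_true(e99["lo"] >= -1 && e99["hi"] <= 1)
  # enormous depth and bulk: the null is nearly degenerate at 0
  ebig <- null_delta_envelope(10000, 10000, 10000, n_sims = 4000, seed = 2)
  expect_lt(ebig["hi"] - ebig["lo"], 0.05)
  expect_identical(null_delta_envelope(45, 45, 20, seed = 3),
                   null_delta_envelope(45, 45, 20, seed = 3))
})

test_that("envelope quantiles match exhaustive enumeration at tiny depth/bulk", {
  # exact null distribution of delta by enumerating every bulk-frequency and
  # read-count outcome, then its type-1 (inverse-ECDF) quantiles
  exact_env <- function(dS, dT, B, level) {
    pool_dist <- function(depth) {
      out <- numeric(0)
      val <- numeric(0)
      for (j in 0:(2 * B)) {
        pf <- dbinom(j, 2 * B, 0.5)
        f <- j / (2 * B)
        for (a in 0:depth) {
          out <- c(out, pf * dbinom(a, depth, f))
          val <- c(val, a / depth)
        }
      }
      tapply(out, val, sum)
    }
    pS <- pool_dist(dS)
    pT <- pool_dist(dT)
    delta <- outer(as.numeric(names(pT)), as.numeric(names(pS)), `-`)
    prob <- outer(as.numeric(pT), as.numeric(pS))
    agg <- tapply(as.numeric(prob), round(as.numeric(delta), 10), sum)
    v <- as.numeric(names(agg))
    cdf <- cumsum(agg)
    qq <- function(q) v[which(cdf >= q - 1e-12)[1]]
    c(lo = qq((1 - level) / 2), hi = qq(1 - (1 - level) / 2))
  }
  for (case in list(c(3, 4, 1), c(5, 5, 2), c(4, 2, 2))) {
    ex <- exact_env(case[1], case[2], case[3], 0.95)
    em <- null_delta_envelope(case[1], case[2], case[3], level = 0.95,
                              n_sims = 2e5, seed = 31)
    expect_equal(unname(em), unname(ex), tolerance = 1e-8)
  }
})

test_that("fresh null sites fall inside their own 95% envelope ~95% of the time", {
  env <- null_delta_envelope(45, 45, 20, level = 0.95, n_sims = 10000,
                             seed = 101)
  set.seed(202)
  fresh <- rnull_delta(10000, 45, 45, 20)
  coverage <- mean(fresh >= env["lo"] & fresh <= env["hi"])
  expect_true(abs(coverage - 0.95) <= 0.01)
})

test_that("candidate screen: absolute window, envelope, and monotonicity", {
  sc <- tiny_scenario(seed = 13, n_genes = 0L, variant_density = 4)
  sites <- simulate_pool_depths(plant_sites(sc, simulate_reference(sc)$genome), sc)
  fit <- bsa_scan(sites, bulk_size = 20, n_sims = 1000, seed = 13)
  rec <- fit$records
  expect_true(all(rec$is_candidate[!is.na(rec$delta)] |
                    abs(rec$delta[!is.na(rec$delta)]) < 0.69 |
                    !rec$passed_filters[!is.na(rec$delta)] |
                    (rec$delta >= rec$null_lo & rec$delta <= rec$null_hi)[!is.na(rec$delta)]))
  expect_true(all(rec$passed_filters[rec$is_candidate]))  # candidates passed filters
  expect_true(all(abs(rec$delta[rec$is_candidate]) >= 0.69))

  # |delta| = 0.5 is never a candidate at the default window
  rec_mid <- rec
  rec_mid$delta <- 0.5
  expect_false(any(screen_candidates(rec_mid)$is_candidate))

  # candidate set shrinks as delta_lo or the confidence level rises
  n_cand <- function(dlo, lvl) {
    sum(bsa_scan(sites, bulk_size = 20, delta_lo = dlo, level = lvl,
                 n_sims = 1000, seed = 13)$counts["candidates"])
  }
  expect_gte(n_cand(0.5, 0.95), n_cand(0.69, 0.95))
  expect_gte(n_cand(0.69, 0.95), n_cand(0.8, 0.95))
  expect_gte(n_cand(0.5, 0.8), n_cand(0.5, 0.999))
})

test_that("a null genome is flagged at no more than the nominal rate", {
  # causal_delta = 0: with the absolute-delta window disabled, the envelope
  # alone should flag ~5% of sites at the 95% level
  sc <- sim_scenario(n_contigs = 1L, contig_length = 100000L, n_genes = 0L,
                     variant_density = 20, causal_delta = 0,
                     causal_pos = 50000L, seed = 14)
  sites <- simulate_pool_depths(plant_sites(sc, simulate_reference(sc)$genome), sc)
  fit <- bsa_scan(sites, bulk_size = 20, delta_lo = 0, n_sims = 4000,
                  seed = 14)
  rec <- fit$records[fit$records$passed_filters, ]
  rate <- mean(rec$is_candidate)
  n <- nrow(rec)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the scan recovers a planted causal locus", {
  # bulk 20, depth 45, causal_delta 0.9, ~50 sites inside the linkage window
  hits <- 0L
  errs <- numeric(0)
  n_runs <- 25L
  for (r in seq_len(n_runs)) {
    sc <- sim_scenario(n_contigs = 1L, contig_length = 100000L, n_genes = 0L,
                       variant_density = 0.5, causal_pos = 50000L,
                       causal_delta = 0.9, linkage_window = 50000L,
                       seed = 1000 + r)
    sites <- simulate_pool_depths(plant_sites(sc, simulate_reference(sc)$genome), sc)
    fit <- bsa_scan(sites, bulk_size = 20, n_sims = 2000, seed = 1000 + r)
    cand <- candidates(fit)
    in_win <- abs(cand$pos - sc$causal_pos) <= sc$linkage_window
    if (any(in_win)) {
      hits <- hits + 1L
      errs <- c(errs, abs(cand$pos[in_win] - sc$causal_pos))
    }
  }
  expect_gte(hits / n_runs, 0.8)
  expect_lt(median(errs), 50000 / 2)
})

test_that("scan object methods print, summarise and convert", {
  sc <- tiny_scenario(seed = 15, n_genes = 0L)
  sites <- simulate_pool_depths(plant_sites(sc, simulate_reference(sc)$genome), sc)
  fit <- bsa_scan(sites, bulk_size = 20, n_sims = 500, seed = 15)
  expect_s3_class(fit, "bsa_scan")
  expect_output(print(fit), "passed filters")
  s <- summary(fit)
  expect_output(print(s), "candidate|quartiles")
  expect_identical(as.data.frame(fit), fit$records)
  expect_equal(nrow(candidates(fit)), unname(fit$counts["candidates"]))
})
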