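test_that("log_likelihood evaluates the count-weighted log template", {
  expect_equal(log_likelihood(c(2, 0), c(0.5, 0.5)), 2 * log(0.5))
  expect_equal(log_likelihood(c(1, 1), c(0.8, 0.2)), log(0.16))
  # uniform template closed form: n * log(1/C)
  counts <- c(3, 4, 5)
  expect_equal(log_likelihood(counts, rep(1 / 3, 3)), 12 * log(1 / 3))
  expect_error(log_likelihood(c(1, 0), c(1, 0)), "smoothing floor")
})

test_that("posterior reproduces hand Bayes results and normalizes", {
  m <- new_cluster_model(c("A", "B"), rbind(c(0.8, 0.2), c(0.2, 0.8)),
                         c(0.5, 0.5), c(TRUE, FALSE), 0)
  r <- posterior(c(1, 0), m)
  expect_equal(unname(r$posteriors), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(r$assigned_phenotype, "A")
  expect_equal(sum(r$posteriors), 1, tolerance = 1e-12)

  # identical templates: likelihood cancels, posterior equals the prior
  m2 <- new_cluster_model(c("A", "B"), rbind(c(0.5, 0.5), c(0.5, 0.5)),
                          c(0.3, 0.7), c(TRUE, FALSE), 0)
  r2 <- posterior(c(4, 9), m2)
  expect_equal(unname(r2$posteriors), c(0.3, 0.7), tolerance = 1e-12)

  expect_error(posterior(c(0, 0), m), "no classifiable mutations")
})

test_that("posterior matches direct product-form Bayes on an exhaustive small grid", {
  # K <= 3 clusters, <= 4 categories, n <= 5: direct evaluation without
  # log-space tricks must agree to 1e-12
  set.seed(5)
  worst <- 0
  for (K in 2:3) {
    for (C in 2:4) {
      for (rep in 1:20) {
        templates <- t(vapply(seq_len(K), function(i) {
          w <- runif(C) + 0.05
          w / sum(w)
        }, numeric(C)))
        priors <- runif(K) + 0.1
        priors <- priors / sum(priors)
        m <- new_cluster_model(paste0("C", 1:K), templates, priors,
                               c(TRUE, rep(FALSE, K - 1)), 0)
        counts <- as.integer(rmultinom(1, sample(1:5, 1), rep(1 / C, C)))
        if (sum(counts) == 0) next
        got <- posterior(counts, m)$posteriors
        want <- oracle_posterior(counts, templates, priors)
        worst <- max(worst, max(abs(got - want)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("posteriors stay normalized for very large mutation loads", {
  spec <- toy_model()
  big <- as.integer(rmultinom(1, 1e5, spec$model$templates[1, ]))
  r <- posterior(big, spec$model)
  expect_equal(sum(r$posteriors), 1, tolerance = 1e-9)
  expect_true(is.finite(r$log_evidence))
  expect_equal(r$assigned_phenotype, "C1")
})

test_that("hrd_probability sums flagged posteriors and call_hrd is strict", {
  post <- rep(0.05, 20)
  m <- new_cluster_model(paste0("C", 1:20), matrix(1 / 2, 20, 2),
                         rep(0.05, 20), c(rep(TRUE, 7), rep(FALSE, 13)), 0)
  r <- structure(list(posteriors = setNames(post, m$cluster_ids)),
                 class = "hrd_posterior")
  expect_equal(hrd_probability(r, m), 0.35)

  expect_true(call_hrd(0.80))
  expect_false(call_hrd(0.79))          # strict inequality at the threshold
  expect_true(call_hrd(0.60, threshold = 0.5))
  expect_error(call_hrd(1.2), "\\[0, 1\\]")
  expect_error(call_hrd(0.5, threshold = -1), "\\[0, 1\\]")
})

test_that("reweight_indels multiplies the indel channel and renormalizes", {
  spec <- toy_model()
  expect_equal(reweight_indels(spec$model, 1)$templates, spec$model$templates)

  # 2-category toy: [0.5 SBS, 0.5 indel], factor 2 -> [1/3, 2/3]
  toy <- new_cluster_model("A", matrix(c(0.5, 0.5), 1), 1, TRUE, 0)
  rw <- reweight_indels(toy, 2, mask = c(FALSE, TRUE))
  expect_equal(unname(rw$templates[1, ]), c(1 / 3, 2 / 3))
  # factor 1/2 then factor 2 returns the original template
  back <- reweight_indels(reweight_indels(toy, 1 / 2, mask = c(FALSE, TRUE)),
                          2, mask = c(FALSE, TRUE))
  expect_equal(back$templates, toy$templates, tolerance = 1e-12)

  # raw mode at factor 1 is also an identity
  expect_equal(reweight_indels(spec$model, 1, mode = "raw")$templates,
               spec$model$templates)
  expect_error(reweight_indels(spec$model, 0), "> 0")
})

test_that("samples drawn from a cluster template are recovered, more so at higher load", {
  spec <- generate_cluster_model(
    n_clusters = 3, hrd_clusters = 1, concentration = 0.5,
    indel_mass = c(0.3, 0.1, 0.05), n_samples = 1L, seed = 13
  )
  tmpl <- spec$model$templates
  tv <- c(tv_dist(tmpl[1, ], tmpl[2, ]), tv_dist(tmpl[1, ], tmpl[3, ]),
          tv_dist(tmpl[2, ], tmpl[3, ]))
  expect_true(all(tv >= 0.3))

  set.seed(17)
  recovery <- vapply(c(25, 50, 100, 500), function(n) {
    hits <- vapply(seq_len(300), function(i) {
      k <- sample(1:3, 1)
      counts <- as.integer(rmultinom(1, n, tmpl[k, ]))
      posterior(counts, spec$model)$assigned_phenotype == paste0("C", k)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(recovery[4], 0.99)
  expect_true(all(diff(recovery) >= -0.02))  # non-decreasing within tolerance
})

test_that("classify_catalog assembles the output table and guards empty samples", {
  spec <- toy_model()
  gc <- generate_catalogs(spec, load_constant = 200, seed = 19)
  calls <- classify_catalog(gc$catalog, spec$model)
  expect_equal(nrow(calls), nrow(gc$catalog))
  expect_true(all(c("sample_id", "C1", "C2", "p_hrd", "assigned_phenotype",
                    "hrd_call", "n_mutations") %in% colnames(calls)))
  expect_equal(calls$p_hrd, calls$C1, tolerance = 1e-12)
  expect_equal(mean(calls$assigned_phenotype == gc$labels), 1)

  withempty <- rbind(gc$catalog, empty = rep(0L, 179))
  expect_error(classify_catalog(withempty, spec$model), "empty")
  ok <- classify_catalog(withempty, spec$model, drop_empty = TRUE)
  expect_equal(attr(ok, "n_empty"), 1L)
  expect_equal(nrow(ok), nrow(gc$catalog))
})
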