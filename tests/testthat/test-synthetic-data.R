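test_that("zero within-cluster spread reproduces the centroids exactly", {
  cfg <- synthetic_config(n_components = 2, n_clusters = 2,
                          within_cluster_sd = c(homo = 0, lumo = 0,
                                                molecular_energy = 0,
                                                adsorption_energy = 0))
  pt <- generate_component_panel(cfg)
  for (i in 1:2) {
    cen <- cfg$cluster_centroids[[pt$truth$component_cluster_labels[i]]]
    row <- pt$panel[i, ]
    expect_equal(row$homo, unname(cen[["homo"]]))
    expect_equal(row$lumo, unname(cen[["lumo"]]))
    expect_equal(row$molecular_energy, unname(cen[["molecular_energy"]]))
    expect_equal(row$adsorption_energy, unname(cen[["adsorption_energy"]]))
    expect_equal(row$electronegativity,
                 (-cen[["homo"]] - cen[["lumo"]]) / 2)
  }
})

test_that("the synthetic dataset is a pure function of its configuration", {
  a <- simulate_mixture_study(synthetic_config(seed = 9))
  b <- simulate_mixture_study(synthetic_config(seed = 9))
  expect_identical(a$panel, b$panel)
  expect_identical(a$mixed, b$mixed)
  expect_identical(a$plate, b$plate)
  c_ <- simulate_mixture_study(synthetic_config(seed = 10))
  expect_false(isTRUE(all.equal(a$panel[, descriptor_names()],
                                c_$panel[, descriptor_names()])))
})

test_that("component labels cover every component once, evenly across clusters", {
  pt <- generate_component_panel(synthetic_config(seed = 4))
  lab <- pt$truth$component_cluster_labels
  expect_equal(length(lab), 8L)
  expect_equal(sort(unique(names(lab))), sort(pt$panel$name[1:8]))
  expect_equal(unname(table(lab)), array(c(4L, 4L)))
})

test_that("the concentration grid is an arithmetic series per component", {
  cfg <- synthetic_config(seed = 6)
  pt <- generate_component_panel(cfg)
  design <- generate_concentration_grid(pt, cfg)
  expect_equal(nrow(design), 72L)                       # 8 x 9
  expect_true(all(design$co_concentration_umol_L == 25))
  for (cm in unique(design$component)) {
    conc <- design$concentration_umol_L[design$component == cm]
    expect_equal(length(conc), 9L)
    expect_equal(unique(diff(conc)), conc[1])           # equally spaced
    expect_true(conc[1] %in% cfg$step_choices)
  }
  # minimal grid
  cfg1 <- synthetic_config(n_components = 1, n_clusters = 1,
                           cluster_centroids = default_cent <- list(
                             c(homo = -6, lumo = -3, molecular_energy = -100,
                               adsorption_energy = -1)),
                           dose_response_params = list(
                             list(intercept = 4, slope = 1, upper = 1,
                                  lower = 0.05,
                                  weights = c(hardness = 0.5))),
                           n_concentrations = 1)
  pt1 <- generate_component_panel(cfg1)
  expect_equal(nrow(generate_concentration_grid(pt1, cfg1)), 1L)
})

test_that("noise-free viability is monotone non-increasing in dose and hits the asymptotes", {
  cfg <- synthetic_config(noise_sd = 0, seed = 8)
  sim <- simulate_mixture_study(cfg)
  for (cm in unique(sim$mixed$component)) {
    v <- sim$mixed$viability[sim$mixed$component == cm]
    expect_true(all(diff(v) <= 1e-12))
  }
  # zero-dose control sits at the upper asymptote
  params <- cfg$dose_response_params[[1]]
  dmix <- matrix(0, 1, 8, dimnames = list(NULL, descriptor_names()))
  expect_equal(expected_viability(dmix, 0, params), params$upper)
  # large-dose limit matches an independent evaluation of the logistic formula
  dmix1 <- as.matrix(sim$mixed[1, descriptor_names()])
  for (dose in c(1e3, 1e6, 1e9)) {
    m <- params$intercept +
      params$weights[["hardness"]] * dmix1[1, "hardness"] +
      params$weights[["adsorption_energy"]] * dmix1[1, "adsorption_energy"]
    oracle <- params$lower + (params$upper - params$lower) /
      (1 + exp(-params$slope * (m - log(dose))))
    expect_equal(expected_viability(dmix1, dose, params), unname(oracle),
                 tolerance = 1e-12)
  }
  expect_lt(expected_viability(dmix1, 1e9, params), params$lower + 1e-3)
})

test_that("viability stays in [0, 1.2] and requires mixed descriptors", {
  sim <- simulate_mixture_study(synthetic_config(noise_sd = 0.3, seed = 12))
  expect_true(all(sim$mixed$viability >= 0 & sim$mixed$viability <= 1.2))
  nomix <- sim$design
  expect_error(generate_viability(nomix, sim$truth), "mixed descriptors")
})

test_that("absorbances round-trip through the viability formula", {
  sim <- simulate_mixture_study(synthetic_config(seed = 5))
  plate <- sim$plate
  s_rec <- compute_viability(plate$a_exp, plate$a_control, plate$a_blank)
  expect_lt(max(abs(s_rec - sim$mixed$viability)), 1e-12)
  # identity cases
  expect_equal(generate_absorbances(data.frame(sample_id = "s",
                                               viability = 1),
                                    0.9, 0.1)$a_exp, 0.9)
  expect_equal(generate_absorbances(data.frame(sample_id = "s",
                                               viability = 0),
                                    0.9, 0.1)$a_exp, 0.1)
  expect_error(generate_absorbances(sim$mixed, 0.1, 0.9), "degenerate")
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synthetic_config(n_components = 1, n_clusters = 2),
               "n_components")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_config(within_cluster_sd = c(homo = -1, lumo = 0,
                                                      molecular_energy = 0,
                                                      adsorption_energy = 0)),
               "within_cluster_sd")
  expect_error(synthetic_config(n_clusters = 0), "n_clusters")
})
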