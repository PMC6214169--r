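test_that("neighbor rates follow the motility/directional construction", {
  tl <- toy_landscape(seed = 1)
  r0 <- build_rates(c(20, 20), 0, rep(0, 4), tl$land, tl$roles)
  expect_equal(unname(r0), rep(1, 4))
  expect_equal(unname(r0 / sum(r0)), rep(0.25, 4))
  ## doubling a motility-only covariate multiplies all four rates by the
  ## same factor and leaves directional probabilities bit-unchanged
  land2 <- make_landscape(2, c(40, 40), 4, seed = 9)
  roles2 <- ctmc_roles(motility = "cov1", directional = "cov2",
                       persistence = TRUE)
  b <- c(-0.5, 0.7, 0.4, 0.2)
  land2x <- land2
  land2x[["cov1"]]$values <- 2 * land2x[["cov1"]]$values
  r1 <- build_rates(c(20, 20), 0, b, land2, roles2, prev_u = c(1, 0))
  r2 <- build_rates(c(20, 20), 0, b, land2x, roles2, prev_u = c(1, 0))
  m <- land2[["cov1"]]$values[21, 21]
  expect_equal(unname(r2), unname(r1) * exp(0.7 * m))
  expect_equal(r2 / sum(r2), r1 / sum(r1), tolerance = 1e-13)
  expect_error(build_rates(c(0, 5), 0, b, tl$land, tl$roles), "edge")
})

test_that("positive directional coefficients orient toward features", {
  ## distance layer to a single feature west of the cell: the rate toward
  ## the neighbor that decreases distance (W) must be largest
  g <- list(nrow = 20L, ncol = 20L, cell_size = 100, origin = c(0, 0))
  dl <- distance_layer(data.frame(x = 250, y = 1050), g, name = "dist")
  land <- raster_stack(dl)
  roles <- ctmc_roles(directional = "dist", persistence = FALSE)
  r <- build_rates(c(10, 10), 0, c(0, 1), land, roles)
  expect_equal(names(which.max(r)), "W")
  expect_gt(r["W"], r["E"])
})

test_that("directional probabilities always sum to one", {
  tl <- toy_landscape(seed = 2)
  set.seed(1)
  for (i in 1:200) {
    cell <- sample(2:37, 2)
    b <- rnorm(4)
    r <- build_rates(cell, runif(1, 0, 24), b, tl$land, tl$roles,
                     prev_u = c(1, 0))
    expect_lt(abs(sum(r / sum(r)) - 1), 1e-12)
  }
})

test_that("latent tables have four rows per transition with one z", {
  tl <- toy_landscape(seed = 3)
  p <- simulate_ctmc_path(tl$land, c(-1, 0.3, 0.3, 0.2), c(20, 20), 48,
                          tl$roles, seed = 1)
  sq <- path_to_seq(p)
  tab <- build_latent_table(sq, tl$land, tl$roles)
  nt <- nrow(sq) - 1
  expect_equal(nrow(tab), 4 * nt)
  expect_equal(sum(tab$z), nt)
  expect_true(all(tapply(tab$z, tab$trans, sum) == 1))
  expect_true(all(tapply(tab$tau, tab$trans, function(x) length(unique(x))) == 1))
  expect_identical(unique(tab$slot[1:4]), c("E", "W", "N", "S"))
  ## single-cell sequence -> empty table
  one <- sq[1, ]
  expect_equal(nrow(build_latent_table(one, tl$land, tl$roles)), 0)
})

test_that("a constructed two-transition table matches hand computation", {
  ## linear covariate c(x, y) = x / 1000 on 100-m cells
  g <- list(nrow = 20L, ncol = 20L, cell_size = 100, origin = c(0, 0))
  xs <- (seq_len(20) - 0.5) * 100
  plane <- covariate_raster(matrix(rep(xs / 1000, each = 20), 20), "plane",
                            cell_size = 100)
  land <- raster_stack(plane)
  roles <- ctmc_roles(motility = "plane", directional = "plane",
                      persistence = TRUE)
  ## cells (10,10) -E-> (10,11) -N-> (11,11); taus 0.5, 0.25 h
  sq <- data.frame(individual_id = "a", draw_index = 1L, segment_id = "s1",
                   row = c(10L, 10L, 11L), col = c(10L, 11L, 11L),
                   tau_hours = c(0.5, 0.25, 0.1),
                   entry_clock_hours = c(0, 0.5, 0.75))
  tab <- build_latent_table(sq, land, roles)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$z, c(1, 0, 0, 0, 0, 0, 1, 0))
  expect_equal(tab$tau, rep(c(0.5, 0.25), each = 4))
  ## transition clock = entry time of the departed cell
  expect_equal(tab$clock, rep(c(0, 0.5), each = 4))
  ## motility value = current cell's covariate
  expect_equal(tab$mot_plane, rep(c(1.05, 1.15), each = 4))
  ## gradient is 0.001 per m -> per-cell-crossing d = -/+0.1 for E/W, 0 N/S
  expect_equal(tab$dir_plane, rep(c(-0.1, 0.1, 0, 0), 2))
  ## persistence: 0 on the first transition; previous direction E on second
  expect_equal(tab$persist, c(0, 0, 0, 0, 1, -1, 0, 0))
})

test_that("per-individual centering and scaling behaves and is unit-invariant", {
  tl <- toy_landscape(seed = 4)
  sq <- rbind(path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 1,
                                             individual_id = "a"), "a", 1L),
              path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 2,
                                             individual_id = "a"), "a", 2L),
              path_to_seq(simulate_ctmc_path(tl$land, c(-1, 0, 0, .2),
                                             c(18, 18), 48, tl$roles, seed = 3,
                                             individual_id = "b"), "b", 1L))
  tab <- build_latent_table(sq, tl$land, tl$roles)
  cs <- center_scale(tab)
  for (id in c("a", "b")) {
    v <- cs$table$mot_cov1[cs$table$individual_id == id & cs$table$slot == "E"]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sd(v) - 1), 1e-12)
  }
  ## intercept and persistence untouched
  expect_identical(cs$table[["(Intercept)"]], tab[["(Intercept)"]])
  expect_identical(cs$table$persist, tab$persist)
  ## the report reapplies to new tables without re-estimation
  again <- apply_scaling(tab, cs$report)
  expect_identical(again$mot_cov1, cs$table$mot_cov1)
  ## km vs m: an affinely rescaled layer gives identical scaled columns
  land_km <- tl$land
  land_km[[1]]$values <- land_km[[1]]$values / 1000
  tab_km <- build_latent_table(sq, land_km, tl$roles)
  cs_km <- center_scale(tab_km)
  expect_equal(cs_km$table$mot_cov1, cs$table$mot_cov1, tolerance = 1e-12)
  expect_equal(cs_km$table$dir_cov1, cs$table$dir_cov1, tolerance = 1e-12)
})

test_that("zero-variance layers are zeroed with a warning, widths preserved", {
  g <- list(nrow = 20L, ncol = 20L, cell_size = 100, origin = c(0, 0))
  flat <- covariate_raster(matrix(1, 20, 20), "flat", cell_size = 100)
  land <- raster_stack(flat)
  roles <- ctmc_roles(motility = "flat", persistence = FALSE)
  sq <- data.frame(individual_id = "a", draw_index = 1L, segment_id = "s1",
                   row = c(10L, 10L, 11L), col = c(10L, 11L, 11L),
                   tau_hours = c(0.5, 0.25, 0.1),
                   entry_clock_hours = c(0, 0.5, 0.75))
  tab <- build_latent_table(sq, land, roles)
  expect_warning(cs <- center_scale(tab), "no variation")
  expect_true(all(cs$table$mot_flat == 0))
  expect_identical(attr(cs$table, "design_cols"), attr(tab, "design_cols"))
})

test_that("the cyclic basis is a periodic partition of unity", {
  for (Q in c(4, 6, 9)) {
    bs <- cyclic_basis(Q)
    tt <- seq(0, 24, by = 0.1)
    W <- bs$eval(tt)
    expect_equal(ncol(W), Q)
    expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
    expect_identical(bs$eval(0), bs$eval(24))
  }
  expect_error(cyclic_basis(3), "Q >= 4")
  expect_error(cyclic_basis(0), ">= 1")
})

test_that("GAM expansion is the Kronecker product of design and basis", {
  tl <- toy_landscape(seed = 5)
  p <- simulate_ctmc_path(tl$land, c(-1, .3, .3, .2), c(20, 20), 24,
                          tl$roles, seed = 2)
  tab <- build_latent_table(path_to_seq(p), tl$land, tl$roles)
  ## Q = 1 constant basis: expanded design identical to the GLM design
  e1 <- expand_gam(tab, cyclic_basis(1))
  for (cl in attr(tab, "design_cols"))
    expect_identical(e1[[paste0(cl, "|q1")]], tab[[cl]])
  ## generic Q: entry (p, q) = x_p * w_q(clock), covariate-major order
  bs <- cyclic_basis(4)
  e4 <- expand_gam(tab, bs)
  expect_length(attr(e4, "design_cols"), 4 * 4)
  W <- bs$eval(tab$clock)
  for (p in attr(tab, "design_cols")) for (q in 1:4)
    expect_equal(e4[[paste0(p, "|q", q)]], tab[[p]] * W[, q])
})

test_that("development interactions multiply through the design", {
  g <- list(nrow = 20L, ncol = 20L, cell_size = 100, origin = c(0, 0))
  xs <- (seq_len(20) - 0.5) * 100
  plane <- covariate_raster(matrix(rep(xs / 1000, each = 20), 20), "plane",
                            cell_size = 100)
  land <- raster_stack(plane)
  roles <- ctmc_roles(motility = "plane", directional = "plane",
                      persistence = FALSE)
  sq <- data.frame(individual_id = "a", draw_index = 1L, segment_id = "s1",
                   row = c(10L, 10L, 11L, 11L), col = c(10L, 11L, 11L, 12L),
                   tau_hours = c(0.5, 0.25, 0.3, 0.1),
                   entry_clock_hours = c(0, 0.5, 0.75, 1.05))
  tab <- build_latent_table(sq, land, roles)
  ## half-developed landscape: columns 11+ developed
  dev <- covariate_raster(matrix(rep(as.numeric(seq_len(20) > 11), each = 20),
                                 20), "dev", cell_size = 100)
  aug <- build_interaction(tab, dev, interact_with = "plane")
  expect_equal(aug$mot_developed, dev$values[cbind(tab$cell_row + 1,
                                                   tab$cell_col + 1)])
  expect_equal(aug[["mot_plane:dev"]], aug$mot_plane * aug$mot_developed)
  expect_equal(aug[["dir_plane:dev"]], aug$dir_plane * aug$mot_developed)
  ## all-undeveloped indicator: interaction columns vanish
  zero <- covariate_raster(matrix(0, 20, 20), "dev0", cell_size = 100)
  aug0 <- build_interaction(tab, zero, interact_with = "plane")
  expect_true(all(aug0$mot_developed == 0))
  expect_true(all(aug0[["mot_plane:dev"]] == 0))
  expect_error(build_interaction(tab, plane, "plane"), "binary")
})
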