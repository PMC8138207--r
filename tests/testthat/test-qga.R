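test_that("rotatable-bond detection excludes rings, amides and terminal groups", {
  expect_length(detect_rotatable_bonds(fx("n_butane")), 1)
  expect_length(detect_rotatable_bonds(fx("benzene")), 0)
  rb <- detect_rotatable_bonds(fx("biphenyl"))
  expect_length(rb, 1)
  # the biphenyl rotatable bond is the inter-ring single bond
  bi <- fx("biphenyl")
  expect_equal(bi$bonds$order[rb], "1")
  expect_true(all(bi$atoms$element[attr(rb, "pairs")] == "C"))
  # n-methylacetamide: the C-N amide bond is excluded, as are both methyls
  nma <- assign_atom_types(molecule(
    data.frame(element = c("C", "C", "O", "N", "C", "H", "H", "H", "H",
                           "H", "H", "H"),
               type = "C",
               x = c(0, 1.5, 2.1, 2.1, 3.5, -0.4, -0.4, -0.4, 2.0, 3.9,
                     3.9, 3.9),
               y = c(0, 0, 1.1, -1.1, -1.2, 0.9, -0.9, 0, -2.0, -0.3,
                     -2.0, -1.2),
               z = c(0, 0, 0, 0, 0, 0.4, 0.4, -0.9, 0, 0.8, 0.4, -1.0)),
    data.frame(i = c(1, 2, 2, 4, 1, 1, 1, 4, 5, 5, 5),
               j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
               order = c("1", "2", "1", "1", rep("1", 7)))))
  expect_length(detect_rotatable_bonds(nma), 0)
})

test_that("encoding saturates at the bounds and round-trips within half a step", {
  bounds <- rbind(c(-pi, pi), c(0, 10))
  expect_true(all(qgadock:::encode_values(bounds[, 1], bounds, 8) == 0))
  expect_true(all(qgadock:::encode_values(bounds[, 2], bounds, 8) == 1))
  expect_error(qgadock:::encode_values(c(0, 11), bounds, 8), "bounds")
  set.seed(5)
  step <- (bounds[, 2] - bounds[, 1]) / (2^16 - 1)
  for (k in 1:50) {
    v <- runif(2, bounds[, 1], bounds[, 2])
    v2 <- qgadock:::decode_values(qgadock:::encode_values(v, bounds, 16),
                                  bounds, 16)
    expect_true(all(abs(v2 - v) <= step / 2 + 1e-12))
  }
  expect_error(qgadock:::decode_values(c(0, 1), bounds, 16), "layout")
})

test_that("pose decoding is rigid: identity genome, pure translation, bond lengths", {
  bu <- fx("n_butane")
  carrier <- build_circular_graphene(10)
  rot <- detect_rotatable_bonds(bu)
  bounds <- default_pose_bounds(carrier, bu, length(rot))
  idg <- pose_genome(rep(0, length(rot)), c(0, 0, 0), c(1, 0, 0, 0), bounds)
  expect_equal(coords(apply_pose(bu, idg, rot)), coords(bu))
  tg <- pose_genome(rep(0, length(rot)), c(2, -1, 5), c(1, 0, 0, 0), bounds)
  moved <- apply_pose(bu, tg, rot)
  expect_equal(colMeans(coords(moved)) - colMeans(coords(bu)), c(2, -1, 5),
               ignore_attr = TRUE)
  # arbitrary pose keeps all bond lengths
  g <- pose_genome(rep(1.2, length(rot)), c(1, 2, 3), c(0.2, -0.7, 0.4, 0.5),
                   bounds)
  posed <- apply_pose(bu, g, rot)
  bp <- cbind(bu$bonds$i, bu$bonds$j)
  d0 <- sqrt(rowSums((coords(bu)[bp[, 1], ] - coords(bu)[bp[, 2], ])^2))
  d1 <- sqrt(rowSums((coords(posed)[bp[, 1], ] - coords(posed)[bp[, 2], ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  # an all-zero quaternion decodes to the identity rotation
  zq <- pose_genome(rep(0, length(rot)), c(0, 0, 0), c(0, 0, 0, 0), bounds)
  expect_equal(coords(apply_pose(bu, zq, rot)), coords(bu))
})

test_that("a fresh population is uniform superposition and measures fairly", {
  cfg <- qga_config(population_size = 7, max_generations = 10)
  pop <- initialize_population(12, cfg)
  expect_length(pop, 7)
  expect_true(all(vapply(pop, function(ch)
    all(ch$thetas == pi / 4), TRUE)))
  # deterministic limits of the measurement rule
  set.seed(3)
  expect_true(all(qgadock:::measure_thetas(rep(0, 100)) == 1))
  expect_true(all(qgadock:::measure_thetas(rep(pi / 2, 100)) == 0))
})

test_that("rotation gate follows the schedule and preserves unitarity", {
  sched <- default_delta_theta_schedule()
  # agreeing bits leave the chromosome unchanged
  ch <- qubit_chromosome(rep(pi / 4, 4), bits = c(0, 1, 0, 1), fitness = 1)
  best <- qubit_chromosome(rep(pi / 4, 4), bits = c(0, 1, 0, 1), fitness = 2)
  out <- apply_qrgo(ch, best, sched, p_qrgo = 1)
  expect_equal(out$thetas, ch$thetas)
  # a pi/4 rotation by +pi/4 reaches the (0, 1) amplitude pair
  sched2 <- data.frame(bit = 1, best_bit = 0, fitness_ge = FALSE,
                       magnitude = pi / 4, target = 0)
  ch2 <- qubit_chromosome(pi / 4, bits = 1, fitness = 0)
  best2 <- qubit_chromosome(0, bits = 0, fitness = 5)
  out2 <- apply_qrgo(ch2, best2, sched2, p_qrgo = 1)
  expect_equal(cos(out2$thetas), 0, tolerance = 1e-12)
  expect_equal(sin(out2$thetas), 1, tolerance = 1e-12)
  # unitarity after arbitrary rotations (exact in theta representation)
  set.seed(9)
  th <- runif(1e4, -2 * pi, 2 * pi)
  dth <- runif(1e4, -pi, pi)
  expect_true(all(abs(cos(th + dth)^2 + sin(th + dth)^2 - 1) < 1e-12))
  expect_error(apply_qrgo(qubit_chromosome(1, bits = 1, fitness = 0),
                          qubit_chromosome(1, bits = 1, fitness = 0),
                          data.frame(bit = 0, best_bit = 0,
                                     fitness_ge = FALSE, magnitude = 0,
                                     target = NA), 1),
               "missing")
})

test_that("NOT gate swaps amplitudes, is an involution and fixes pi/4", {
  th <- atan2(0.8, 0.6)  # (alpha, beta) = (0.6, 0.8)
  ch <- qubit_chromosome(th)
  out <- apply_qngo(ch, p_qngo = 1)
  expect_equal(cos(out$thetas), 0.8, tolerance = 1e-12)
  expect_equal(sin(out$thetas), 0.6, tolerance = 1e-12)
  expect_equal(apply_qngo(out, p_qngo = 1)$thetas, ch$thetas)
  expect_equal(apply_qngo(qubit_chromosome(pi / 4), p_qngo = 1)$thetas, pi / 4)
})

test_that("crossover conserves the theta multiset and self-crossover is identity", {
  set.seed(21)
  c1 <- qubit_chromosome(runif(20)); c2 <- qubit_chromosome(runif(20))
  out <- crossover(c1, c2, p_crossover = 1)
  expect_equal(sort(c(out[[1]]$thetas, out[[2]]$thetas)),
               sort(c(c1$thetas, c2$thetas)))
  self <- crossover(c1, c1, p_crossover = 1)
  expect_equal(self[[1]]$thetas, c1$thetas)
  expect_error(crossover(c1, qubit_chromosome(runif(5))), "mismatch")
})

test_that("catastrophe reinitializes the population but the archive survives", {
  set.seed(2)
  pop <- lapply(1:5, function(k) qubit_chromosome(runif(8), bits = rep(1, 8),
                                                  fitness = k))
  fresh <- catastrophe(pop)
  ref <- initialize_population(8, qga_config(population_size = 5,
                                             max_generations = 1))
  expect_equal(lapply(fresh, `[[`, "thetas"), lapply(ref, `[[`, "thetas"))
  # driver-level archive retention across a catastrophe: constant objective
  cfg <- qga_config(population_size = 6, max_generations = 60,
                    bits_per_variable = 4, stagnation_window = 50,
                    seed = 7, top_k = 2)
  res <- qga_optimize(function(v) 1.0, rbind(c(0, 1)), cfg)
  expect_equal(res$catastrophes, 51)
  expect_equal(res$archive[[1]]$fitness, 1.0)
  expect_equal(res$generations, 60)  # max_generations honoured
})

test_that("best-so-far fitness is non-decreasing and fixed seeds reproduce runs", {
  f <- function(v) -sum((v - 0.4)^2)
  bounds <- rbind(c(0, 1), c(0, 1))
  cfg <- qga_config(population_size = 10, max_generations = 40,
                    bits_per_variable = 8, seed = 123)
  r1 <- qga_optimize(f, bounds, cfg)
  r2 <- qga_optimize(f, bounds, cfg)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$avg_fitness, r2$avg_fitness)
  expect_true(all(diff(r1$best_fitness) >= 0))
  expect_lte(length(r1$avg_fitness), 40)
})

test_that("rotation pressure pulls the population toward the best string", {
  # with mutation and crossover off, expected Hamming distance to the best
  # bits does not increase over evolution
  f <- function(v) -sum((v - 0.85)^2)
  bounds <- rbind(c(0, 1))
  dist_trace <- function(seed) {
    cfg <- qga_config(population_size = 12, max_generations = 30,
                      bits_per_variable = 8, p_qngo = 0, p_crossover = 0,
                      seed = seed, use_catastrophe = FALSE)
    res <- qga_optimize(f, bounds, cfg)
    res$avg_fitness
  }
  improved <- vapply(1:6, function(s) {
    tr <- dist_trace(s)
    mean(utils::tail(tr, 5)) >= mean(utils::head(tr, 5))
  }, TRUE)
  expect_gte(sum(improved), 5)
})

test_that("convergence termination stops a stagnant run early", {
  cfg <- qga_config(population_size = 6, max_generations = 500,
                    bits_per_variable = 4, use_catastrophe = FALSE,
                    check_convergence = TRUE, convergence_window = 20,
                    seed = 4)
  res <- qga_optimize(function(v) 2.5, rbind(c(0, 1)), cfg)
  expect_true(res$converged)
  expect_equal(res$generations, 21)  # 20 stagnant diffs after generation 1
})
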