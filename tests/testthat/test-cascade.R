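# a cheap deterministic landscape: energy depends only on the ligand
# centroid's distance from a target point above the carrier
centroid_mock <- function(target = c(0, 0, 3.5)) {
  mock_engine(function(pose) {
    cen <- colMeans(coords(pose$ligand))
    energy_report(sum((cen - target)^2) - 30, E_G = -10, E_lig = -5)
  })
}

test_that("seeded chromosomes reproduce their source bits", {
  cfg <- qga_config(population_size = 20, max_generations = 1)
  bits <- lapply(1:10, function(k) as.integer(rbinom(16, 1, 0.5)))
  pop <- seed_population(bits, cfg, epsilon = 0)
  expect_length(pop, 20)
  # epsilon = 0: measurement is deterministic
  for (k in 1:10) {
    ch <- measure_chromosome(pop[[k]])
    expect_equal(ch$bits, bits[[k]])
  }
  # the remaining slots are fresh pi/4 chromosomes
  for (k in 11:20) expect_true(all(pop[[k]]$thetas == pi / 4))
  # epsilon = 0.5 seeds are indistinguishable from fresh ones
  pop2 <- seed_population(bits, cfg, epsilon = 0.5)
  expect_true(all(abs(pop2[[1]]$thetas - pi / 4) < 1e-12))
  expect_error(seed_population(rep(bits, 3), cfg), "population slots")
  expect_error(seed_population(list(c(0L, 1L)), cfg, n_bits = 16), "length")
})

test_that("mock engines satisfy the binding-energy arithmetic", {
  eng <- mock_engine(function(pose) energy_report(-30, E_G = -10,
                                                  E_lig = -10))
  rep <- eng$score(complex_pose(fx("coronene_patch"), fx("benzene")))
  expect_equal(rep$E_Delta, -10)
})

test_that("a single-layer cascade reproduces a plain QGA run", {
  carrier <- fx("coronene_patch"); lig <- fx("benzene")
  eng <- centroid_mock()
  cfg <- qga_config(population_size = 8, max_generations = 15, seed = 42,
                    top_k = 3)
  casc <- cascade_config(list(list(engine = eng, config = cfg)),
                         migration_count = 3)
  res_c <- run_cascade(carrier, lig, casc)
  res_q <- run_qga(carrier, lig, cfg, eng)
  expect_equal(res_c$best_fitness, res_q$best$fitness)
  expect_equal(res_c$layers[[1]]$avg_fitness, res_q$avg_fitness)
})

test_that("migrated seeds give the refined layer a head start", {
  carrier <- fx("coronene_patch"); lig <- fx("benzene")
  eng <- centroid_mock()
  wins <- 0
  for (s in 1:10) {
    cfg1 <- qga_config(population_size = 10, max_generations = 25, seed = s,
                       top_k = 10)
    r1 <- run_qga(carrier, lig, cfg1, eng)
    cfg2 <- qga_config(population_size = 10, max_generations = 2, top_k = 10)
    seeded <- run_qga(carrier, lig, cfg2, eng,
                      initial_bits = lapply(r1$archive, `[[`, "bits"),
                      seeding_bias = 0.05)
    # layer-2 initial best vs layer-1 random-initialization average
    if (seeded$best_fitness[1] >= r1$avg_fitness[1]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("the default cascade mirrors the recommended layer parameters", {
  casc <- default_cascade_config(ff_engine(), centroid_mock())
  expect_length(casc$layers, 2)
  expect_equal(casc$layers[[1]]$config$max_generations, 5000)
  expect_equal(casc$layers[[1]]$config$population_size, 100)
  expect_equal(casc$layers[[2]]$config$max_generations, 500)
  expect_equal(casc$layers[[2]]$config$population_size, 20)
  expect_equal(casc$migration_count, 10)
  expect_true(casc$layers[[1]]$config$use_catastrophe)
  expect_false(casc$layers[[1]]$config$check_convergence)
  expect_false(casc$layers[[2]]$config$use_catastrophe)
  expect_true(casc$layers[[2]]$config$check_convergence)
  # probabilities follow the published defaults
  expect_equal(casc$layers[[1]]$config$p_qrgo, 0.5)
  expect_equal(casc$layers[[1]]$config$p_qngo, 0.1)
  expect_equal(casc$layers[[1]]$config$p_crossover, 0.7)
})

test_that("two-layer runs persist traces and poses and reproduce bit-for-bit", {
  carrier <- fx("coronene_patch"); lig <- fx("benzene")
  eng <- centroid_mock()
  mk <- function() cascade_config(list(
    list(engine = eng, config = qga_config(population_size = 8,
                                           max_generations = 10, seed = 31,
                                           top_k = 4)),
    list(engine = eng, config = qga_config(population_size = 8,
                                           max_generations = 5, top_k = 4))),
    migration_count = 4)
  wd1 <- withr::local_tempdir(); wd2 <- withr::local_tempdir()
  r1 <- run_cascade(carrier, lig, mk(), workdir = wd1)
  r2 <- run_cascade(carrier, lig, mk(), workdir = wd2)
  expect_equal(r1$best_fitness, r2$best_fitness)
  expect_true(file.exists(file.path(wd1, "layer_1", "gen_trace.tsv")))
  expect_true(file.exists(file.path(wd1, "layer_2", "best_1.mol2")))
  f1 <- readLines(file.path(wd1, "layer_2", "best_1.mol2"))
  f2 <- readLines(file.path(wd2, "layer_2", "best_1.mol2"))
  expect_identical(f1, f2)
  # the final layer's best is at least as good as the migrated layer-1 best
  # when both are scored by the same (final) engine
  expect_gte(r2$best_fitness, r2$layers[[1]]$best$fitness - 1e-9)
})

test_that("the external-command adapter parses energies and reports failures", {
  wd <- withr::local_tempdir()
  script <- file.path(wd, "fake_engine.sh")
  writeLines(c("#!/bin/sh",
               "natoms=$(head -1 \"$1\")",
               "echo \"TOTAL ENERGY = -0.5 Eh\" > \"$2\""), script)
  Sys.chmod(script, "0755")
  eng <- external_engine(command = paste("sh", script, "{input}", "{output}"),
                         energy_pattern = "TOTAL ENERGY = (-?[0-9.]+)",
                         unit_to_kcal = 627.509474)
  pose <- complex_pose(fx("coronene_patch"), fx("benzene"))
  rep <- external_engine_energy(pose, eng)
  expect_equal(rep$E_GDDS, -0.5 * 627.509474)
  expect_equal(rep$E_Delta, 0.5 * 627.509474)  # -0.5 - (-0.5) - (-0.5)
  # nonzero exit must not yield a partial report
  bad <- external_engine(command = "/nonexistent_engine_binary {input} {output}",
                         energy_pattern = "(-?[0-9.]+)")
  expect_error(external_engine_energy(pose, bad))
  # unparseable output is reported with the captured text
  noise <- file.path(wd, "noise.sh")
  writeLines(c("#!/bin/sh", "echo no numbers here > \"$2\""), noise)
  eng2 <- external_engine(command = paste("sh", noise, "{input}", "{output}"),
                          energy_pattern = "ENERGY = (-?[0-9.]+)")
  expect_error(external_engine_energy(pose, eng2), "parse")
})
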