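# Multi-fidelity cascade: run a cheap QGA layer with fine parameters, migrate
# its best chromosomes to seed the initial population of a more accurate (and
# more expensive) layer run with coarse parameters. Engines are pluggable so
# the accurate layer can be an external quantum-chemistry program.

#' Specify an energy engine for a cascade layer
#'
#' Three kinds: \code{"internal_ff"} (the native force field),
#' \code{"mock"} (a deterministic user function, for tests and dry runs) and
#' \code{"external_command"} (any program driven through a command template).
#'
#' @param kind engine kind.
#' @param fun for \code{mock}: a function taking a [complex_pose()] (or the
#'   posed ligand coordinate matrix, whichever signature it declares first
#'   argument \code{pose}) and returning either an [energy_report()] or a
#'   single number interpreted as E_GDDS.
#' @param command for \code{external_command}: a command template containing
#'   the placeholders \code{{input}} and \code{{output}}; the input is an XYZ
#'   file of the fragment to evaluate.
#' @param energy_pattern regular expression with one capture group extracting
#'   the energy from the program's output file (falls back to standard
#'   output).
#' @param unit_to_kcal multiplicative conversion from the engine's energy unit
#'   to kcal/mol (e.g. 627.509474 for hartree).
#' @return a \code{qga_engine}.
#' @export
engine_spec <- function(kind = c("internal_ff", "mock", "external_command"),
                        fun = NULL, command = NULL, energy_pattern = NULL,
                        unit_to_kcal = 1) {
  kind <- match.arg(kind)
  switch(kind,
         internal_ff = ff_engine(),
         mock = mock_engine(fun),
         external_command = external_engine(command, energy_pattern,
                                            unit_to_kcal))
}

#' Mock energy engine
#'
#' Wraps a deterministic function for tests, toy landscapes and cascade dry
#' runs. The function receives the [complex_pose()] and returns an
#' [energy_report()] or a number (taken as E_GDDS with zero fragment
#' energies).
#'
#' @param fun the energy function.
#' @return a \code{qga_engine} of kind \code{"mock"}.
#' @export
mock_engine <- function(fun) {
  if (!is.function(fun)) stop("mock engine requires a deterministic energy function")
  eng <- list(kind = "mock")
  eng$score <- function(pose) {
    out <- fun(pose)
    if (inherits(out, "energy_report")) out
    else energy_report(as.numeric(out), E_G = 0, E_lig = 0)
  }
  eng$prepare <- function(carrier, ligand) {
    function(lig_xyz) {
      posed <- ligand
      coords(posed) <- lig_xyz
      eng$score(complex_pose(carrier, posed))
    }
  }
  structure(eng, class = "qga_engine")
}

#' External-command energy engine
#'
#' Writes geometries to XYZ (with total formal charge and multiplicity 1 on
#' the comment line), substitutes them into the command template, runs it and
#' parses the energy back. The binding energy comes from three evaluations:
#' complex, carrier and ligand.
#'
#' @inheritParams engine_spec
#' @param workdir directory for scratch files (default a session tempdir).
#' @return a \code{qga_engine} of kind \code{"external_command"}.
#' @export
external_engine <- function(command, energy_pattern, unit_to_kcal = 1,
                            workdir = NULL) {
  if (is.null(command)) stop("external engine requires a command template")
  if (is.null(energy_pattern)) stop("external engine requires an energy pattern")
  eng <- list(kind = "external_command", command = command,
              energy_pattern = energy_pattern, unit_to_kcal = unit_to_kcal,
              workdir = workdir)
  run_one <- function(m, wd, tag) {
    input <- file.path(wd, paste0(tag, ".xyz"))
    output <- file.path(wd, paste0(tag, ".out"))
    write_xyz(m, input)
    cmd <- gsub("{input}", input, eng$command, fixed = TRUE)
    cmd <- gsub("{output}", output, cmd, fixed = TRUE)
    res <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stop("external engine command failed (exit ", status, "):\n",
           paste(res, collapse = "\n"))
    text <- if (file.exists(output)) readLines(output, warn = FALSE) else res
    hit <- regmatches(text, regexec(eng$energy_pattern, text))
    vals <- unlist(lapply(hit, function(h) if (length(h) >= 2) h[2] else NULL))
    if (!length(vals))
      stop("could not parse an energy from the external engine output:\n",
           paste(utils::tail(text, 20), collapse = "\n"))
    as.numeric(vals[length(vals)]) * eng$unit_to_kcal
  }
  eng$score <- function(pose) {
    wd <- if (is.null(eng$workdir)) tempfile("qgadock_ext") else eng$workdir
    dir.create(wd, showWarnings = FALSE, recursive = TRUE)
    combined <- merge_structures(pose$carrier, pose$ligand)
    energy_report(run_one(combined, wd, "complex"),
                  E_G = run_one(pose$carrier, wd, "carrier"),
                  E_lig = run_one(pose$ligand, wd, "ligand"))
  }
  eng$prepare <- function(carrier, ligand) {
    function(lig_xyz) {
      posed <- ligand
      coords(posed) <- lig_xyz
      eng$score(complex_pose(carrier, posed))
    }
  }
  structure(eng, class = "qga_engine")
}

#' Evaluate a pose with an external engine
#'
#' Convenience wrapper matching the engine's \code{score} method.
#'
#' @param pose a [complex_pose()].
#' @param engine a \code{qga_engine} from [external_engine()].
#' @return an [energy_report()].
#' @export
external_engine_energy <- function(pose, engine) engine$score(pose)

# concatenate two structures into one (no bonds between fragments)
merge_structures <- function(a, b) {
  off <- n_atoms(a)
  bonds_b <- b$bonds
  if (nrow(bonds_b)) { bonds_b$i <- bonds_b$i + off; bonds_b$j <- bonds_b$j + off }
  molecule(rbind(a$atoms, b$atoms), rbind(a$bonds, bonds_b),
           name = paste0(a$name, "+", b$name))
}

#' Seed a qubit population from migrated bit strings
#'
#' Builds one chromosome per migrated string with qubit angles chosen so
#' measurement reproduces the source bit with probability 1 - epsilon
#' (epsilon = 0 is deterministic, epsilon = 0.5 is indistinguishable from a
#' fresh chromosome); the remaining population slots are filled with fresh
#' pi/4 chromosomes.
#'
#' @param bits_list list of 0/1 integer vectors.
#' @param config a [qga_config()] (supplies the population size and the
#'   measurement polarity).
#' @param n_bits chromosome length (defaults to the first string's length).
#' @param epsilon seeding bias probability margin.
#' @return list of [qubit_chromosome()] objects of length
#'   \code{population_size}.
#' @export
seed_population <- function(bits_list, config, n_bits = NULL,
                            epsilon = 0.05) {
  if (!length(bits_list)) stop("no bit strings to seed from")
  if (is.null(n_bits)) n_bits <- length(bits_list[[1]])
  if (length(bits_list) > config$population_size)
    stop("more migrated strings than population slots")
  if (any(vapply(bits_list, length, 0L) != n_bits))
    stop("seed string length does not match the chromosome layout")
  # P(measure 1) = cos^2(theta) under the default polarity
  th1 <- acos(sqrt(1 - epsilon))   # reproduce bit 1
  th0 <- acos(sqrt(epsilon))       # reproduce bit 0
  if (identical(config$measurement_polarity, "alpha0")) {
    tmp <- th1; th1 <- th0; th0 <- tmp
  }
  seeded <- lapply(bits_list, function(bitv)
    qubit_chromosome(ifelse(bitv == 1, th1, th0)))
  fresh <- replicate(config$population_size - length(seeded),
                     qubit_chromosome(rep(pi / 4, n_bits)), simplify = FALSE)
  c(seeded, fresh)
}

#' Configure a cascade protocol
#'
#' @param layers ordered list; each element is \code{list(engine =, config =)}
#'   with a \code{qga_engine} and a [qga_config()].
#' @param migration_count best chromosomes passed from each layer to seed the
#'   next (default 10).
#' @param seeding_bias epsilon: probability that a seeded qubit measures
#'   opposite to its source bit (default 0.05, near-deterministic but not
#'   frozen).
#' @return list of class \code{cascade_config}.
#' @export
cascade_config <- function(layers, migration_count = 10, seeding_bias = 0.05) {
  if (length(layers) < 1) stop("cascade needs at least one layer")
  for (ly in layers)
    stopifnot(inherits(ly$engine, "qga_engine"), inherits(ly$config, "qga_config"))
  structure(list(layers = layers, migration_count = migration_count,
                 seeding_bias = seeding_bias),
            class = "cascade_config")
}

#' Default two-layer cascade configuration
#'
#' Mirrors the recommended protocol: a fine, cheap first layer (5000
#' generations, population 100, catastrophe on, no convergence stop, so it
#' keeps producing diverse optima) followed by a coarse accurate layer (500
#' generations, population 20, catastrophe off, convergence stop on), with
#' the 10 best chromosomes migrating.
#'
#' @param engine1 energy engine of the cheap layer (default [ff_engine()]).
#' @param engine2 energy engine of the accurate layer.
#' @param seed RNG seed applied to layer 1 (layer 2 continues the stream).
#' @param generations1,population1,generations2,population2 layer sizes.
#' @return a [cascade_config()].
#' @export
default_cascade_config <- function(engine1 = ff_engine(), engine2,
                                   seed = NULL,
                                   generations1 = 5000, population1 = 100,
                                   generations2 = 500, population2 = 20) {
  cascade_config(list(
    list(engine = engine1,
         config = qga_config(population_size = population1,
                             max_generations = generations1,
                             use_catastrophe = TRUE,
                             check_convergence = FALSE, seed = seed)),
    list(engine = engine2,
         config = qga_config(population_size = population2,
                             max_generations = generations2,
                             use_catastrophe = FALSE,
                             check_convergence = TRUE))))
}

#' Run a cascade protocol
#'
#' Layer 1 starts from a fresh population; every later layer is seeded with
#' the previous layer's best \code{migration_count} chromosomes (re-scored
#' under the new engine on arrival). Per-layer traces and best poses can be
#' persisted under \code{workdir/layer_k/}.
#'
#' @param carrier,ligand structures with types/charges assigned.
#' @param cascade a [cascade_config()].
#' @param workdir optional directory for \code{gen_trace.tsv} and
#'   \code{best_i.mol2} files per layer.
#' @return list of class \code{cascade_result}: \code{layers} (per-layer
#'   \code{qga_result}), \code{best_pose} ([complex_pose()] with
#'   \code{energy}), \code{best_fitness}.
#' @export
run_cascade <- function(carrier, ligand, cascade, workdir = NULL) {
  stopifnot(inherits(cascade, "cascade_config"))
  results <- list()
  seeds_bits <- NULL
  for (k in seq_along(cascade$layers)) {
    ly <- cascade$layers[[k]]
    init <- NULL
    if (!is.null(seeds_bits)) {
      n_take <- min(cascade$migration_count, length(seeds_bits))
      init <- seeds_bits[seq_len(n_take)]
    }
    res <- tryCatch(
      run_qga(carrier, ligand, ly$config, ly$engine, initial_bits = init,
              seeding_bias = cascade$seeding_bias),
      error = function(e) stop(sprintf("cascade layer %d failed: %s", k,
                                       conditionMessage(e)), call. = FALSE))
    results[[k]] <- res
    if (!is.null(workdir)) {
      lw <- file.path(workdir, sprintf("layer_%d", k))
      dir.create(lw, showWarnings = FALSE, recursive = TRUE)
      write_qga_trace(res, file.path(lw, "gen_trace.tsv"))
      for (p in seq_along(res$poses))
        write_mol2(res$poses[[p]]$ligand,
                   file.path(lw, sprintf("best_%d.mol2", p)),
                   energies = res$poses[[p]]$energy)
    }
    seeds_bits <- lapply(res$archive, `[[`, "bits")
  }
  final <- results[[length(results)]]
  structure(list(layers = results,
                 best_pose = final$poses[[1]],
                 best_fitness = final$best$fitness),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d layer(s); final best fitness %.4f\n",
              length(x$layers), x$best_fitness))
  cat(sprintf("  best E_Delta: %.4f kcal/mol\n", x$best_pose$energy$E_Delta))
  invisible(x)
}
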