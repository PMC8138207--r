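# Quantum genetic algorithm. Each chromosome is a vector of qubit angles
# theta (alpha = cos theta, beta = sin theta, so alpha^2 + beta^2 = 1 holds
# exactly). Measurement collapses each qubit to a classical bit; the rotation
# gate nudges qubits toward the best chromosome's bits, the NOT gate swaps
# amplitudes (mutation), single-point crossover exchanges theta segments and
# the catastrophe operator reinitializes the whole population when the
# average fitness stagnates.

#' QGA configuration
#'
#' @param population_size chromosomes per generation.
#' @param max_generations evolution cap.
#' @param p_qrgo per-chromosome probability of the quantum rotation gate.
#' @param p_qngo per-qubit mutation probability of the quantum NOT gate.
#' @param p_crossover per-pair probability of single-point crossover.
#' @param stagnation_window consecutive stagnant generations (average-fitness
#'   change below \code{convergence_threshold}) that trigger the catastrophe
#'   operator.
#' @param convergence_threshold fitness-change threshold (default 0.001).
#' @param convergence_window consecutive stagnant generations that terminate
#'   the run when \code{check_convergence} is on; kept longer than the
#'   catastrophe window so a reinitialization gets a chance to escape first.
#' @param use_catastrophe logical; reinitialize on stagnation.
#' @param check_convergence logical; terminate on prolonged stagnation.
#' @param bits_per_variable quantization width of each real variable.
#' @param delta_theta_schedule rotation-angle lookup table; see
#'   [default_delta_theta_schedule()].
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param fitness_mode \code{"potential"} (fitness = -E_GDDS, the default) or
#'   \code{"binding"} (fitness = -E_Delta).
#' @param measurement_polarity \code{"alpha1"} measures bit 1 with probability
#'   alpha^2 (the default operational rule); \code{"alpha0"} flips it.
#' @param top_k archive size (best chromosomes retained across generations
#'   and catastrophes).
#' @return list of class \code{qga_config}.
#' @export
qga_config <- function(population_size = 100, max_generations = 5000,
                       p_qrgo = 0.5, p_qngo = 0.1, p_crossover = 0.7,
                       stagnation_window = 50, convergence_threshold = 0.001,
                       convergence_window = 100,
                       use_catastrophe = TRUE, check_convergence = FALSE,
                       bits_per_variable = 16,
                       delta_theta_schedule = default_delta_theta_schedule(),
                       seed = NULL, fitness_mode = c("potential", "binding"),
                       measurement_polarity = c("alpha1", "alpha0"),
                       top_k = 10) {
  fitness_mode <- match.arg(fitness_mode)
  measurement_polarity <- match.arg(measurement_polarity)
  stopifnot(p_qrgo >= 0, p_qrgo <= 1, p_qngo >= 0, p_qngo <= 1,
            p_crossover >= 0, p_crossover <= 1,
            population_size >= 2, max_generations >= 1)
  structure(as.list(environment()), class = "qga_config")
}

#' Default rotation-angle schedule
#'
#' Lookup table of the rotation gate: rows are keyed by (own bit, best
#' chromosome's bit, own fitness >= best fitness); \code{magnitude} is the
#' unsigned rotation (radians) and \code{target} the bit pole to rotate
#' toward (NA = leave the qubit alone). Agreeing bits are left unchanged;
#' a chromosome worse than the best rotates by 0.05 pi toward the best's bit,
#' one at least as good reinforces its own bit by 0.01 pi. The sign of the
#' applied rotation is derived from the quadrant of (alpha, beta) so the
#' rotation always moves the amplitude toward the targeted pole. Users may
#' supply any table with these columns.
#'
#' @return data.frame with columns \code{bit}, \code{best_bit},
#'   \code{fitness_ge}, \code{magnitude}, \code{target}.
#' @export
default_delta_theta_schedule <- function() {
  data.frame(
    bit = c(0, 0, 1, 1, 0, 0, 1, 1),
    best_bit = c(0, 0, 1, 1, 1, 1, 0, 0),
    fitness_ge = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    magnitude = c(0, 0, 0, 0, 0.05 * pi, 0.01 * pi, 0.05 * pi, 0.01 * pi),
    target = c(NA, NA, NA, NA, 1, 0, 0, 1))
}

#' A qubit chromosome
#'
#' @param thetas qubit angles (radians); \code{alpha = cos(theta)},
#'   \code{beta = sin(theta)}.
#' @param bits measured classical bits (filled by [measure_chromosome()]).
#' @param fitness fitness of the decoded bits.
#' @return list of class \code{qubit_chromosome}.
#' @export
qubit_chromosome <- function(thetas, bits = NULL, fitness = NA_real_) {
  structure(list(thetas = as.numeric(thetas), bits = bits, fitness = fitness),
            class = "qubit_chromosome")
}

#' Initialize a qubit population
#'
#' Every qubit angle starts at pi/4, i.e. alpha = beta = cos(pi/4): both
#' ground states are equally likely on measurement.
#'
#' @param n_bits qubits per chromosome.
#' @param config a [qga_config()].
#' @return list of \code{population_size} [qubit_chromosome()] objects.
#' @export
initialize_population <- function(n_bits, config) {
  replicate(config$population_size,
            qubit_chromosome(rep(pi / 4, n_bits)), simplify = FALSE)
}

# vector primitives shared by the chromosome-level operators and the driver ---

measure_thetas <- function(thetas, polarity = "alpha1") {
  u <- stats::runif(length(thetas))
  p1 <- cos(thetas)^2
  if (polarity == "alpha0") p1 <- 1 - p1
  as.integer(u < p1)
}

# signed rotation toward a target pole; target 1 maximizes alpha^2 = cos^2,
# target 0 maximizes beta^2 = sin^2 (under the alpha1 measurement rule)
qrgo_deltas <- function(thetas, bits, best_bits, fitness_ge, schedule,
                        polarity = "alpha1") {
  key <- paste(bits, best_bits, fitness_ge)
  skey <- paste(schedule$bit, schedule$best_bit, schedule$fitness_ge)
  row <- match(key, skey)
  if (anyNA(row)) stop("delta-theta schedule is missing an entry")
  mag <- schedule$magnitude[row]
  target <- schedule$target[row]
  if (polarity == "alpha0" && length(target)) target <- 1 - target
  s <- sign(cos(thetas) * sin(thetas))
  d <- numeric(length(thetas))
  tow1 <- !is.na(target) & target == 1
  tow0 <- !is.na(target) & target == 0
  d[tow1] <- -mag[tow1] * s[tow1]
  d[tow0] <- mag[tow0] * s[tow0]
  # on a pole boundary (alpha or beta exactly 0) pick the positive direction
  # unless the qubit already sits on the targeted pole
  amb1 <- tow1 & s == 0 & abs(cos(thetas)) < 0.5
  amb0 <- tow0 & s == 0 & abs(sin(thetas)) < 0.5
  d[amb1] <- mag[amb1]
  d[amb0] <- mag[amb0]
  d
}

#' Measure a chromosome
#'
#' Collapses every qubit to a classical bit: draw u in [0, 1); the bit is 1
#' when u < alpha^2 (default polarity). The measured string is stored on the
#' chromosome.
#'
#' @param chromosome a [qubit_chromosome()].
#' @param polarity see [qga_config()].
#' @return the chromosome with \code{bits} filled.
#' @export
measure_chromosome <- function(chromosome, polarity = "alpha1") {
  chromosome$bits <- measure_thetas(chromosome$thetas, polarity)
  chromosome
}

#' Apply the quantum rotation gate operator toward the best chromosome
#'
#' With probability \code{p_qrgo} the chromosome's qubits are rotated by the
#' scheduled angles: theta' = theta + delta, i.e. (alpha', beta') =
#' (cos(theta + delta), sin(theta + delta)), which preserves
#' alpha^2 + beta^2 = 1 exactly.
#'
#' @param chromosome measured and scored [qubit_chromosome()].
#' @param best the best chromosome (measured and scored).
#' @param schedule rotation schedule (see [default_delta_theta_schedule()]).
#' @param p_qrgo application probability.
#' @param polarity measurement polarity in force.
#' @return the (possibly rotated) chromosome.
#' @export
apply_qrgo <- function(chromosome, best, schedule = default_delta_theta_schedule(),
                       p_qrgo = 1, polarity = "alpha1") {
  if (stats::runif(1) >= p_qrgo) return(chromosome)
  if (is.null(chromosome$bits) || is.null(best$bits))
    stop("both chromosomes must be measured before QRGO")
  d <- qrgo_deltas(chromosome$thetas, chromosome$bits, best$bits,
                   isTRUE(chromosome$fitness >= best$fitness), schedule,
                   polarity)
  chromosome$thetas <- chromosome$thetas + d
  chromosome
}

#' Apply the quantum NOT gate operator (mutation)
#'
#' Each qubit is swapped, (alpha, beta) -> (beta, alpha) i.e.
#' theta -> pi/2 - theta, independently with probability \code{p_qngo}.
#' Applying it twice restores the qubit; theta = pi/4 is a fixed point.
#'
#' @param chromosome a [qubit_chromosome()].
#' @param p_qngo per-qubit probability.
#' @return the mutated chromosome.
#' @export
apply_qngo <- function(chromosome, p_qngo = 1) {
  hit <- stats::runif(length(chromosome$thetas)) < p_qngo
  chromosome$thetas[hit] <- pi / 2 - chromosome$thetas[hit]
  chromosome
}

#' Single-point crossover of two chromosomes
#'
#' With probability \code{p_crossover}, draws a cut position uniformly in
#' 0..L and swaps the theta segments after it; a cut at 0 or L returns the
#' parents intact. The multiset of theta values across the pair is conserved.
#'
#' @param c1,c2 [qubit_chromosome()] objects of equal length.
#' @param p_crossover application probability.
#' @return list of the two offspring.
#' @export
crossover <- function(c1, c2, p_crossover = 1) {
  L <- length(c1$thetas)
  if (length(c2$thetas) != L) stop("chromosome length mismatch")
  if (stats::runif(1) < p_crossover) {
    cut <- sample(0:L, 1)
    if (cut > 0 && cut < L) {
      seg <- (cut + 1):L
      tmp <- c1$thetas[seg]
      c1$thetas[seg] <- c2$thetas[seg]
      c2$thetas[seg] <- tmp
    }
  }
  list(c1, c2)
}

#' Catastrophe operator
#'
#' Reinitializes every qubit of every chromosome to pi/4. The best-so-far
#' chromosome survives only in the external archive, never in the population.
#'
#' @param population list of chromosomes.
#' @return the reinitialized population.
#' @export
catastrophe <- function(population) {
  lapply(population, function(ch) {
    ch$thetas[] <- pi / 4
    ch$bits <- NULL
    ch$fitness <- NA_real_
    ch
  })
}

#' Fitness of a pose under an energy report
#'
#' Mode \code{"potential"}: fitness = -E_GDDS; mode \code{"binding"}:
#' fitness = -E_Delta. Lower energy is strictly higher fitness.
#'
#' @param report an [energy_report()].
#' @param mode fitness mode.
#' @return dimensionless fitness.
#' @export
fitness_from_report <- function(report, mode = c("potential", "binding")) {
  mode <- match.arg(mode)
  if (mode == "potential") -1.0 * report$E_GDDS else -1.0 * report$E_Delta
}

# archive of the best chromosomes; ties broken by earliest generation then
# lowest chromosome index (insertion order does both)
archive_update <- function(archive, bits, fitness, generation, index, top_k) {
  key <- paste(bits, collapse = "")
  hit <- match(key, vapply(archive, `[[`, "", "key"))
  if (!is.na(hit)) return(archive)
  archive[[length(archive) + 1]] <- list(key = key, bits = bits,
                                         fitness = fitness,
                                         generation = generation,
                                         index = index)
  ord <- order(-vapply(archive, `[[`, 0, "fitness"),
               vapply(archive, `[[`, 0, "generation"),
               vapply(archive, `[[`, 0, "index"))
  archive[ord][seq_len(min(top_k, length(archive)))]
}

#' Run the QGA over an arbitrary objective
#'
#' The generic optimization core: real variables are quantized to qubit
#' strings, and the population evolves by measurement, fitness evaluation,
#' rotation toward the archived best, NOT-gate mutation, crossover and
#' (optionally) catastrophe, until \code{max_generations} or convergence.
#'
#' @param objective function mapping a real variable vector to a fitness
#'   (maximized).
#' @param bounds 2-column (min, max) matrix, one row per variable.
#' @param config a [qga_config()].
#' @param initial_bits optional list of bit vectors seeded into the initial
#'   population (see [seed_population()]).
#' @param seeding_bias epsilon handed to [seed_population()] when
#'   \code{initial_bits} is given.
#' @return list of class \code{qga_result}: \code{best} (list with
#'   \code{bits}, \code{values}, \code{fitness}), \code{archive},
#'   \code{avg_fitness} and \code{best_fitness} per-generation traces,
#'   \code{catastrophes} (generations where the operator fired),
#'   \code{generations} run, and \code{converged}.
#' @export
qga_optimize <- function(objective, bounds, config = qga_config(),
                         initial_bits = NULL, seeding_bias = 0.05) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nv <- nrow(bounds)
  L <- nv * config$bits_per_variable
  pop <- if (is.null(initial_bits)) initialize_population(L, config)
         else seed_population(initial_bits, config, n_bits = L,
                              epsilon = seeding_bias)
  archive <- list()
  avg_trace <- best_trace <- numeric()
  cat_events <- integer()
  stag <- conv <- 0L
  converged <- FALSE
  for (gen in seq_len(config$max_generations)) {
    vals <- numeric(config$population_size)
    for (k in seq_along(pop)) {
      pop[[k]] <- measure_chromosome(pop[[k]], config$measurement_polarity)
      v <- decode_values(pop[[k]]$bits, bounds, config$bits_per_variable)
      pop[[k]]$fitness <- objective(v)
      vals[k] <- pop[[k]]$fitness
      archive <- archive_update(archive, pop[[k]]$bits, pop[[k]]$fitness,
                                gen, k, config$top_k)
    }
    avg <- mean(vals)
    avg_trace <- c(avg_trace, avg)
    best_trace <- c(best_trace, archive[[1]]$fitness)
    # termination / stagnation bookkeeping on consecutive average changes
    if (gen > 1) {
      if (abs(avg - avg_trace[gen - 1]) < config$convergence_threshold) {
        stag <- stag + 1L; conv <- conv + 1L
      } else {
        stag <- 0L; conv <- 0L
      }
    }
    if (config$check_convergence && conv >= config$convergence_window) {
      converged <- TRUE
      break
    }
    if (gen == config$max_generations) break
    best_ch <- qubit_chromosome(numeric(L), bits = archive[[1]]$bits,
                                fitness = archive[[1]]$fitness)
    for (k in seq_along(pop))
      pop[[k]] <- apply_qrgo(pop[[k]], best_ch, config$delta_theta_schedule,
                             config$p_qrgo, config$measurement_polarity)
    for (k in seq_along(pop))
      pop[[k]] <- apply_qngo(pop[[k]], config$p_qngo)
    pairing <- sample(config$population_size)
    for (k in seq_len(config$population_size %/% 2)) {
      i <- pairing[2 * k - 1]; j <- pairing[2 * k]
      out <- crossover(pop[[i]], pop[[j]], config$p_crossover)
      pop[[i]] <- out[[1]]; pop[[j]] <- out[[2]]
    }
    if (config$use_catastrophe && stag >= config$stagnation_window) {
      pop <- catastrophe(pop)
      cat_events <- c(cat_events, gen)
      stag <- 0L
    }
  }
  best <- archive[[1]]
  structure(list(
    best = list(bits = best$bits,
                values = decode_values(best$bits, bounds,
                                       config$bits_per_variable),
                fitness = best$fitness),
    archive = archive,
    avg_fitness = avg_trace, best_fitness = best_trace,
    catastrophes = cat_events, generations = length(avg_trace),
    converged = converged, bounds = bounds, config = config),
    class = "qga_result")
}

#' @export
print.qga_result <- function(x, ...) {
  cat(sprintf(paste0("<qga_result> %d generations, best fitness %.4f, ",
                     "%d catastrophe(s)%s\n"),
              x$generations, x$best$fitness, length(x$catastrophes),
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' QGA pose search for a carrier/ligand pair
#'
#' Encodes the ligand's rotatable-bond torsions, translation and quaternion
#' rotation as a qubit chromosome and evolves the population against the
#' given energy engine. The carrier is rigid throughout.
#'
#' @param carrier carrier \code{qmol} with types/charges assigned.
#' @param ligand ligand \code{qmol} with types/charges assigned.
#' @param config a [qga_config()].
#' @param engine an energy engine ([ff_engine()], [mock_engine()] or
#'   [external_engine()]).
#' @param initial_bits optional seed chromosomes (bit vectors), e.g. migrated
#'   from a cheaper cascade layer.
#' @param seeding_bias epsilon for [seed_population()].
#' @return a \code{qga_result} whose \code{poses} field holds the archive
#'   decoded to [complex_pose()] objects with [energy_report()]s.
#' @export
run_qga <- function(carrier, ligand, config = qga_config(),
                    engine = ff_engine(), initial_bits = NULL,
                    seeding_bias = 0.05) {
  rot <- detect_rotatable_bonds(ligand)
  bounds <- default_pose_bounds(carrier, ligand, length(rot))
  evalr <- engine$prepare(carrier, ligand)
  objective <- function(v) {
    g <- values_to_genome(v, length(rot), bounds)
    posed <- apply_pose(ligand, g, rot)
    rep <- evalr(coords(posed))
    fitness_from_report(rep, config$fitness_mode)
  }
  res <- qga_optimize(objective, bounds, config, initial_bits, seeding_bias)
  res$poses <- lapply(res$archive, function(entry) {
    cp <- decode_chromosome(entry$bits, carrier, ligand, rot, bounds,
                            config$bits_per_variable)
    cp$energy <- evalr(coords(cp$ligand))
    cp
  })
  res
}

#' Write the per-generation trace of a QGA run as TSV
#'
#' Columns: generation, average fitness, best-so-far fitness, catastrophe
#' flag. Suitable for plotting convergence curves.
#'
#' @param result a \code{qga_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qga_trace <- function(result, path) {
  df <- data.frame(generation = seq_along(result$avg_fitness),
                   avg_fitness = result$avg_fitness,
                   best_fitness = result$best_fitness,
                   catastrophe = as.integer(
                     seq_along(result$avg_fitness) %in% result$catastrophes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
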