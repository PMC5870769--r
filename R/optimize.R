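# Bounded differential-evolution parameter fitting, scored by superposed
# backbone RMSD. DE variant: rand/1/bin with clipping at the bounds and
# greedy selection; a single seed governs all stochastic draws so runs are
# exactly reproducible (and evaluation order cannot affect selection).

#' A bounded search dimension
#'
#' @param name parameter name, matching a builder parameter field. Elements
#'   of per-chain/per-helix vector fields are addressed with an index
#'   suffix, e.g. `"z_shift_2"`.
#' @param lower,upper bounds (lower < upper).
#' @param kind "continuous" (default) or "integer" (rounded at evaluation
#'   time).
#' @return A `ParameterSpec` list.
#' @export
parameter_spec <- function(name, lower, upper,
                           kind = c("continuous", "integer")) {
  kind <- match.arg(kind)
  if (!isTRUE(lower < upper)) {
    stop("parameter '", name, "': lower bound must be below upper bound")
  }
  structure(list(name = name, lower = lower, upper = upper, kind = kind),
            class = "ParameterSpec")
}

#' Differential-evolution settings
#'
#' @param population number of models per generation (>= 4).
#' @param generations number of generations (>= 1).
#' @param seed integer seed governing all stochastic draws.
#' @param F differential weight in (0, 2); default 0.75.
#' @param CR crossover rate in `[0, 1]`; default 0.8.
#' @return An `OptimizerConfig` list.
#' @export
optimizer_config <- function(population = 20, generations = 50, seed = 1,
                             F = 0.75, CR = 0.8) {
  if (!isTRUE(population >= 4)) stop("population must be >= 4")
  if (!isTRUE(generations >= 1)) stop("generations must be >= 1")
  if (!isTRUE(F > 0 && F < 2)) stop("F must lie in (0, 2)")
  if (!isTRUE(CR >= 0 && CR <= 1)) stop("CR must lie in [0, 1]")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 seed = as.integer(seed), F = F, CR = CR),
            class = "OptimizerConfig")
}

#' Total number of models evaluated by a run
#'
#' One parent generation plus one candidate population per generation:
#' `population * (generations + 1)`. For the standard budgets this gives
#' 1020 (20 x 50), 1530 (30 x 50), 2550 (50 x 50) and 4040 (40 x 100)
#' models including the parent generation.
#'
#' @param population models per generation (>= 1).
#' @param generations number of generations (>= 0).
#' @export
total_evaluations <- function(population, generations) {
  stopifnot(population >= 1, generations >= 0)
  as.integer(population) * (as.integer(generations) + 1L)
}

# evaluate a function under a local RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Run bounded differential evolution (rand/1/bin)
#'
#' The parent population is sampled uniformly in the bounding box. Each
#' generation, every member i receives a mutant a + F (b - c) built from
#' three distinct other members, crossed over binomially at rate CR with
#' one forced dimension; candidates are clipped to the bounds and replace
#' their parent only when not worse (greedy selection). Deterministic for a
#' given seed.
#'
#' @param objective function taking a named numeric vector of parameters and
#'   returning a finite score to minimize.
#' @param specs list of `ParameterSpec` (>= 1).
#' @param cfg an `OptimizerConfig`.
#' @return A `FitResult`: `best_params` (named vector), `best_score`,
#'   `history` (best score after the parent generation and after each
#'   generation; non-increasing), `n_evaluations` = population *
#'   (generations + 1), and `population`/`scores` (final state).
#' @export
run_de <- function(objective, specs, cfg = optimizer_config()) {
  if (inherits(specs, "ParameterSpec")) specs <- list(specs)
  if (!length(specs)) stop("at least one ParameterSpec is required")
  stopifnot(inherits(cfg, "OptimizerConfig"))
  nm <- vapply(specs, `[[`, "", "name")
  lo <- vapply(specs, `[[`, 0, "lower")
  hi <- vapply(specs, `[[`, 0, "upper")
  is_int <- vapply(specs, `[[`, "", "kind") == "integer"
  d <- length(nm)
  np <- cfg$population
  evl <- function(x) {
    x[is_int] <- round(x[is_int])
    names(x) <- nm
    objective(x)
  }
  with_local_seed(cfg$seed, {
    pop <- matrix(runif(np * d, lo, hi), nrow = np, ncol = d, byrow = TRUE)
    scores <- apply(pop, 1, evl)
    if (mean(!is.finite(scores)) > 0.5) {
      stop("objective was non-finite on more than half of the parent ",
           "population; review the parameter ranges")
    }
    scores[!is.finite(scores)] <- Inf
    history <- numeric(cfg$generations + 1)
    history[1] <- min(scores)
    for (g in seq_len(cfg$generations)) {
      for (i in seq_len(np)) {
        abc <- sample(seq_len(np)[-i], 3)
        mutant <- pop[abc[1], ] + cfg$F * (pop[abc[2], ] - pop[abc[3], ])
        cross <- runif(d) < cfg$CR
        cross[sample.int(d, 1)] <- TRUE
        cand <- ifelse(cross, mutant, pop[i, ])
        cand <- pmin(pmax(cand, lo), hi)
        sc <- evl(cand)
        if (is.finite(sc) && sc <= scores[i]) {
          pop[i, ] <- cand
          scores[i] <- sc
        }
      }
      history[g + 1] <- min(scores)
    }
    best <- which.min(scores)
    bp <- pop[best, ]
    bp[is_int] <- round(bp[is_int])
    names(bp) <- nm
    structure(list(best_params = bp, best_score = scores[best],
                   history = history,
                   n_evaluations = total_evaluations(np, cfg$generations),
                   population = pop, scores = scores),
              class = "FitResult")
  })
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("<FitResult: best score %.4g after %d evaluations>\n",
              x$best_score, x$n_evaluations))
  print(round(x$best_params, 4))
  invisible(x)
}

# fields that are per-chain / per-helix vectors in the builder params
VECTOR_PARAM_FIELDS <- c("z_shift", "chain_rotation", "n_residues",
                         "orientation", "axis_distance", "phi_ca", "splay",
                         "off_plane_rotation", "helix_lengths")

# merge named optimizer values (possibly index-suffixed) into a params list
merge_params <- function(fixed, values) {
  for (nm in names(values)) {
    m <- regmatches(nm, regexec("^(.*)_([0-9]+)$", nm))[[1]]
    if (length(m) == 3 && m[2] %in% VECTOR_PARAM_FIELDS) {
      k <- as.integer(m[3])
      vec <- fixed[[m[2]]] %||% numeric(0)
      if (length(vec) < k) vec <- c(vec, rep(0, k - length(vec)))
      vec[k] <- values[[nm]]
      fixed[[m[2]]] <- vec
    } else {
      fixed[[nm]] <- values[[nm]]
    }
  }
  fixed
}

SPEC_BUILDERS <- list(
  coiled_coil = function(params) {
    cls <- params$helix_class %||% "alpha"
    params$helix_class <- NULL
    build_coiled_coil(do.call(crick_params, params), cls = cls)
  },
  tropocollagen = function(params) {
    params$superhelix_handedness <- params$superhelix_handedness %||% "right"
    build_tropocollagen(do.call(crick_params, params))
  },
  helix_pair = function(params) build_helix_pair(do.call(helix_pair_params,
                                                         params)),
  solenoid = function(params) build_solenoid(do.call(solenoid_params,
                                                     params)),
  dna_duplex = function(params) build_dna_duplex(do.call(dna_duplex_params,
                                                         params))
)

#' Build a model from a named specification and a parameter document
#'
#' @param spec_name one of "coiled_coil", "tropocollagen", "helix_pair",
#'   "solenoid", "dna_duplex".
#' @param params named list of builder parameters (field names as in the
#'   corresponding `*_params()` constructor).
#' @return An `Assembly`.
#' @export
build_specification <- function(spec_name, params) {
  b <- SPEC_BUILDERS[[spec_name]]
  if (is.null(b)) {
    stop("unknown specification '", spec_name, "'; available: ",
         paste(names(SPEC_BUILDERS), collapse = ", "))
  }
  b(params)
}

#' Names of the available building specifications
#' @export
specification_names <- function() names(SPEC_BUILDERS)

# hydroxyproline is treated as proline for fitting (it does not change the
# gross backbone geometry being fitted)
preprocess_target <- function(target) {
  target$atoms$mol_code[target$atoms$mol_code == "HYP"] <- "PRO"
  target
}

#' Fit a specification's parameters to a target structure
#'
#' Runs differential evolution with objective equal to the superposed
#' backbone RMSD between the built model and the target. Chain and residue
#' counts of the model are taken from the target (for the coiled-coil and
#' collagen specifications) and checked before optimization starts.
#' Hydroxyproline residues in the target are treated as proline.
#'
#' @param target a backbone-complete `Assembly`.
#' @param spec_name specification id (see [specification_names()]).
#' @param fixed named list of parameters held fixed during the fit.
#' @param ranges list of `ParameterSpec` giving the free dimensions, or the
#'   name of a packaged default range set (see [default_ranges()]).
#' @param cfg an `OptimizerConfig`.
#' @return A `FitResult` with `best_rmsd` (Å), `best_model` (the rebuilt
#'   `Assembly`) and `rmsd100` added.
#' @export
fit_structure <- function(target, spec_name, fixed = list(), ranges,
                          cfg = optimizer_config()) {
  target <- preprocess_target(target)
  if (is.character(ranges)) ranges <- default_ranges(ranges)
  if (spec_name %in% c("coiled_coil", "tropocollagen")) {
    chains <- chain_ids(target)
    fixed$n_chains <- fixed$n_chains %||% length(chains)
    fixed$n_residues <- fixed$n_residues %||%
      vapply(chains, function(ch) n_residues(target, ch), integer(1))
  }
  target_bb <- backbone_coords(target)
  mid <- lapply(ranges, function(s) (s$lower + s$upper) / 2)
  names(mid) <- vapply(ranges, `[[`, "", "name")
  trial <- build_specification(spec_name, merge_params(fixed, mid))
  check_compatible(trial, target)
  objective <- function(values) {
    model <- build_specification(spec_name, merge_params(fixed, as.list(values)))
    kabsch_rmsd(backbone_coords(model), target_bb)
  }
  fit <- run_de(objective, ranges, cfg)
  fit$best_rmsd <- fit$best_score
  fit$best_model <- build_specification(spec_name,
                                        merge_params(fixed,
                                                     as.list(fit$best_params)))
  nres <- nrow(target_bb) / 4
  fit$rmsd100 <- if (nres >= 20) rmsd100(fit$best_rmsd, nres) else NA_real_
  fit$spec_name <- spec_name
  fit$fixed <- fixed
  fit
}

check_compatible <- function(model, target) {
  cm <- chain_ids(model)
  ct <- chain_ids(target)
  nm <- vapply(cm, function(ch) n_residues(model, ch), integer(1))
  nt <- vapply(ct, function(ch) n_residues(target, ch), integer(1))
  if (length(nm) != length(nt) || any(nm != nt)) {
    stop("specification output does not match the target: model chains [",
         paste(sprintf("%s:%d", cm, nm), collapse = ", "), "] vs target [",
         paste(sprintf("%s:%d", ct, nt), collapse = ", "), "]")
  }
  invisible(TRUE)
}

#' Two-stage solenoid fit
#'
#' Stage 1 fits a two-helix repeating unit (helix-pair specification)
#' against one repeat of the target; stage 2 fixes the optimized unit and
#' fits the solenoid's helical-symmetry parameters (radius, rise, twist,
#' unit rotation) against the full target. The target's chains are split
#' into `n_repeats` consecutive equal groups to define the repeats. Stage
#' seeds derive from `cfg1`/`cfg2` (when `cfg2$seed` equals `cfg1$seed` the
#' second stage uses seed + 1, so one seed governs both stages).
#'
#' @param target a backbone-complete `Assembly` of `n_repeats` identical
#'   repeats.
#' @param n_repeats number of repeats in the target (>= 2).
#' @param unit_ranges `ParameterSpec` list for the helix-pair stage.
#' @param solenoid_ranges `ParameterSpec` list for the symmetry stage.
#' @param cfg1,cfg2 `OptimizerConfig` for the two stages.
#' @return The stage-2 `FitResult`, with the stage-1 result attached as
#'   `$stage1`.
#' @export
two_stage_solenoid_fit <- function(target, n_repeats, unit_ranges,
                                   solenoid_ranges,
                                   cfg1 = optimizer_config(50, 50),
                                   cfg2 = optimizer_config(40, 100)) {
  target <- preprocess_target(target)
  chains <- chain_ids(target)
  if (length(chains) %% n_repeats != 0) {
    stop("target has ", length(chains), " chains, not divisible into ",
         n_repeats, " repeats")
  }
  per <- length(chains) / n_repeats
  if (per != 2) {
    stop("the helix-pair unit expects 2 chains per repeat; target has ",
         per)
  }
  first <- lapply(chains[seq_len(per)], function(ch) get_polymer(target, ch))
  unit_target <- relabel(combine_assemblies(first, id = "repeat_1"))
  lens <- vapply(chain_ids(unit_target),
                 function(ch) n_residues(unit_target, ch), integer(1))
  stage1 <- fit_structure(unit_target, "helix_pair",
                          fixed = list(helix_lengths = lens),
                          ranges = unit_ranges, cfg = cfg1)
  if (cfg2$seed == cfg1$seed) cfg2$seed <- cfg1$seed + 1L
  stage2 <- fit_structure(target, "solenoid",
                          fixed = list(repeat_unit = stage1$best_model,
                                       n_repeats = n_repeats),
                          ranges = solenoid_ranges, cfg = cfg2)
  stage2$stage1 <- stage1
  stage2
}

#' Packaged default parameter ranges
#'
#' The standard range sets used by the rebuild-and-fit protocols, keyed by
#' fold: coiled-coil oligomer states dimer/trimer/tetramer/pentamer
#' (superhelix radius 3.5-5.5 / 5.0-7.0 / 5.5-8.5 / 6.5-9.5 Å, pitch
#' 50-350 Å, interface angle -20 to 20 degrees), collagen (radius 1.5-5.5,
#' pitch 25-105, unrestricted interface angle, per-chain z-shift 0.0-6.2 Å
#' and rotational offset -30 to 30 degrees) and the two ankyrin-like
#' solenoid stages (unit: per-helix axis distance 0.0-6.0 Å, z-shift -6.0
#' to 6.0 Å, unrestricted spin, in-plane -45 to 5 and out-of-plane 90-270
#' degrees; solenoid: radius 25.0-45.0 Å, rise 2.0-18.0 Å, unrestricted
#' twist and unit rotation).
#'
#' @param set one of "dimer", "trimer", "tetramer", "pentamer", "collagen",
#'   "ankyrin_unit", "ankyrin_solenoid".
#' @return A list of `ParameterSpec`.
#' @export
default_ranges <- function(set = c("dimer", "trimer", "tetramer", "pentamer",
                                   "collagen", "ankyrin_unit",
                                   "ankyrin_solenoid")) {
  set <- match.arg(set)
  ps <- parameter_spec
  radii <- list(dimer = c(3.5, 5.5), trimer = c(5.0, 7.0),
                tetramer = c(5.5, 8.5), pentamer = c(6.5, 9.5))
  if (set %in% names(radii)) {
    r <- radii[[set]]
    return(list(ps("superhelix_radius", r[1], r[2]),
                ps("pitch", 50, 350),
                ps("interface_angle", -20, 20)))
  }
  if (set == "collagen") {
    out <- list(ps("superhelix_radius", 1.5, 5.5),
                ps("pitch", 25, 105),
                ps("interface_angle", -180, 180))
    for (k in 1:3) {
      out <- c(out, list(ps(paste0("z_shift_", k), 0.0, 6.2),
                         ps(paste0("chain_rotation_", k), -30, 30)))
    }
    return(out)
  }
  if (set == "ankyrin_unit") {
    out <- list()
    for (k in 1:2) {
      out <- c(out, list(ps(paste0("axis_distance_", k), 0.0, 6.0),
                         ps(paste0("z_shift_", k), -6.0, 6.0),
                         ps(paste0("phi_ca_", k), -180, 180),
                         ps(paste0("splay_", k), -45, 5),
                         ps(paste0("off_plane_rotation_", k), 90, 270)))
    }
    return(out)
  }
  list(ps("radius", 25.0, 45.0),
       ps("rise_per_repeat", 2.0, 18.0),
       ps("twist_per_repeat", -180, 180),
       ps("unit_rotation", -180, 180))
}
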