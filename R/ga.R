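# Genetic algorithm over fusion weight vectors.
#
# An organism is a point on the weight simplex. Fitness is the F-measure of
# the thresholded ensemble against the annotated ground truth. Evolution uses
# 40 % elitism, 2-vs-2 tournament selection among the elite, two crossover
# operators scheduled over the run (naive early, domination late), gentle and
# super mutation, and a domination threshold that super-mutates any child
# with a single overwhelming weight.

.renorm <- function(w) {
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}

#' Genetic algorithm configuration
#'
#' Defaults follow the study conditions: 100 organisms, 200 generations,
#' 100 repeated runs, 40 % elitism, 20 % child and 10 % elite gentle-mutation
#' chance, rank threshold 0.50 and domination threshold 0.85; the crossover
#' operator switches from naive to domination halfway through the run.
#'
#' @param population_size organisms per generation.
#' @param generations generations per run.
#' @param runs independent repeated runs (averaged in the report).
#' @param elitism_rate fraction of the population preserved each generation.
#' @param child_mutation_prob gentle-mutation chance for each new child.
#' @param elite_mutation_prob gentle-mutation chance for each elite member
#'   (applied before reinsertion).
#' @param rank_threshold ensemble classification cut-off used by the fitness.
#' @param domination_threshold weight ceiling; a child exceeding it in any
#'   slot is super-mutated.
#' @param crossover_switch_fraction fraction of generations after which
#'   domination crossover replaces naive crossover.
#' @param rng_seed base seed; run r uses \code{rng_seed + r - 1}.
#' @return list of class \code{"ga_config"}.
#' @export
ga_config <- function(population_size = 100L, generations = 200L,
                      runs = 100L, elitism_rate = 0.40,
                      child_mutation_prob = 0.20,
                      elite_mutation_prob = 0.10,
                      rank_threshold = 0.50,
                      domination_threshold = 0.85,
                      crossover_switch_fraction = 0.5,
                      rng_seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations), runs = as.integer(runs),
              elitism_rate = elitism_rate,
              child_mutation_prob = child_mutation_prob,
              elite_mutation_prob = elite_mutation_prob,
              rank_threshold = rank_threshold,
              domination_threshold = domination_threshold,
              crossover_switch_fraction = crossover_switch_fraction,
              rng_seed = as.integer(rng_seed))
  probs <- c(cfg$elitism_rate, cfg$child_mutation_prob,
             cfg$elite_mutation_prob, cfg$rank_threshold,
             cfg$domination_threshold)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$crossover_switch_fraction > 0,
            cfg$crossover_switch_fraction < 1,
            cfg$population_size >= 1L, cfg$generations >= 0L,
            cfg$runs >= 1L)
  structure(cfg, class = "ga_config")
}

#' Static fitness context for a GA run
#'
#' Precomputes the normalised score matrix over the ground-truth universe and
#' the positive-label mask, so every fitness evaluation is a single
#' matrix-vector product and a threshold comparison.
#'
#' @param norm_scores list of named normalised score vectors, one per method
#'   (see \code{\link{normalize_ranking}}).
#' @param gt a \code{"ground_truth"}.
#' @return list of class \code{"ga_context"} with \code{R} (|U| x methods),
#'   \code{positive} (logical |U|), \code{terms}.
#' @export
ga_context <- function(norm_scores, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  R <- score_matrix(norm_scores, gt$universe)
  structure(list(R = R, positive = gt$universe %in% gt$positives,
                 terms = gt$universe, n_methods = length(norm_scores)),
            class = "ga_context")
}

#' Fitness of one weight vector
#'
#' F-measure of the terms whose ensemble score reaches the rank threshold,
#' judged against the context's ground truth.
#'
#' @param w weight vector on the simplex.
#' @param ctx a \code{"ga_context"}.
#' @param rank_threshold classification cut-off (default 0.50).
#' @return F-measure in [0, 1].
#' @export
ga_fitness <- function(w, ctx, rank_threshold = 0.50) {
  check_weights(w, ctx$n_methods)
  .fitness_matrix(matrix(w, nrow = 1L), ctx, rank_threshold)[1L]
}

# fitness of many organisms at once; W is organisms x methods
.fitness_matrix <- function(W, ctx, rank_threshold) {
  if (!length(ctx$terms)) return(rep(0, nrow(W)))
  scores <- ctx$R %*% t(W)                      # |U| x organisms
  predicted <- scores >= rank_threshold
  tp <- as.numeric(colSums(predicted & ctx$positive))
  fp <- as.numeric(colSums(predicted & !ctx$positive))
  fn <- as.numeric(colSums(!predicted & ctx$positive))
  denom <- 2 * tp + fp + fn
  ifelse(denom > 0, 2 * tp / denom, 0)
}

#' Naive crossover
#'
#' Child 1 is the elementwise product of the parents' weights, child 2 their
#' elementwise sum, each renormalised to the simplex (divide by sum — the
#' only normalisation preserving the sum-to-1 invariant). Used in the early
#' stages of the run to keep the population diverse.
#'
#' @param p1,p2 parent weight vectors on the simplex.
#' @return list of two child weight vectors.
#' @examples
#' naive_crossover(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
#' # child1 (10/29, 9/29, 10/29); child2 (0.35, 0.30, 0.35)
#' @export
naive_crossover <- function(p1, p2) {
  check_weights(p1, length(p1)); check_weights(p2, length(p1))
  list(.renorm(p1 * p2), .renorm(p1 + p2))
}

#' Domination crossover
#'
#' Child 1 places the largest of the parents' individual weights in its own
#' slot and splits the remainder evenly over the other slots; child 2 does
#' the same with the second largest parental weight. Ties resolve to the
#' lower slot index, then to the first parent. Used late in the run to
#' concentrate fitness.
#'
#' @param p1,p2 parent weight vectors on the simplex.
#' @return list of two child weight vectors.
#' @examples
#' domination_crossover(c(0.1, 0.2, 0.7), c(0.6, 0.3, 0.1))
#' # child1 (0.15, 0.15, 0.7); child2 (0.6, 0.2, 0.2)
#' @export
domination_crossover <- function(p1, p2) {
  check_weights(p1, length(p1)); check_weights(p2, length(p1))
  k <- length(p1)
  vals <- c(p1, p2)
  slots <- c(seq_len(k), seq_len(k))
  parents <- rep(1:2, each = k)
  ord <- order(-vals, slots, parents)
  make_child <- function(entry) {
    w <- rep((1 - vals[entry]) / (k - 1), k)
    w[slots[entry]] <- vals[entry]
    w
  }
  list(make_child(ord[1L]), make_child(ord[2L]))
}

#' Gentle and super mutation
#'
#' Gentle mutation redraws a single uniformly chosen weight uniformly on
#' [0, 1] and renormalises; super mutation redraws all weights. A degenerate
#' all-zero draw renormalises to the uniform vector. Uses R's global RNG:
#' seed with \code{set.seed} for reproducibility.
#'
#' @param w weight vector on the simplex.
#' @param mode \code{"gentle"} or \code{"super"}.
#' @return mutated weight vector on the simplex.
#' @export
mutate_weights <- function(w, mode = c("gentle", "super")) {
  mode <- match.arg(mode)
  if (mode == "gentle") {
    slot <- sample.int(length(w), 1L)
    w[slot] <- stats::runif(1)
  } else {
    w <- stats::runif(length(w))
  }
  .renorm(w)
}

#' Draw a random simplex point
#'
#' Independent uniform draws renormalised to sum 1.
#'
#' @param k number of weights.
#' @return weight vector on the simplex.
#' @export
random_weights <- function(k = 3L) .renorm(stats::runif(k))

#' Advance a population by one generation
#'
#' The top \code{elitism_rate} organisms by fitness form the elite. Children
#' are produced by repeatedly drawing four distinct elite parents, running
#' two 2-vs-2 tournaments (higher fitness wins, ties broken at random) and
#' crossing the two winners with the scheduled operator (naive early,
#' domination late). Each child gently mutates with probability
#' \code{child_mutation_prob}; a child whose final weights exceed the
#' domination threshold in any slot is super-mutated. When the children fill
#' the non-elite share of the population, the (individually, with probability
#' \code{elite_mutation_prob}, gently mutated) elite is appended.
#'
#' @param pop matrix of organisms (rows) by weights (columns).
#' @param fitness numeric fitness per organism.
#' @param cfg a \code{"ga_config"}.
#' @param generation 1-based index of the generation being produced.
#' @return matrix of the next generation's organisms (same shape).
#' @export
evolve_generation <- function(pop, fitness, cfg, generation = 1L) {
  n <- nrow(pop)
  k <- ncol(pop)
  elite_n <- max(1L, round(n * cfg$elitism_rate))
  if (elite_n < 4L)
    stop("population too small: the elite must hold at least 4 organisms ",
         "for tournament selection")
  n_children <- n - elite_n
  ord <- order(-fitness)
  elite <- pop[ord[seq_len(elite_n)], , drop = FALSE]
  use_naive <- generation <= cfg$crossover_switch_fraction * cfg$generations
  children <- matrix(NA_real_, n_children, k)
  filled <- 0L
  while (filled < n_children) {
    idx <- sample.int(elite_n, 4L)
    duel <- function(i, j) {
      fi <- fitness[ord[idx[i]]]; fj <- fitness[ord[idx[j]]]
      if (fi > fj) idx[i] else if (fj > fi) idx[j]
      else if (stats::runif(1) < 0.5) idx[i] else idx[j]
    }
    w1 <- duel(1L, 2L); w2 <- duel(3L, 4L)
    kids <- if (use_naive)
      naive_crossover(elite[w1, ], elite[w2, ])
    else domination_crossover(elite[w1, ], elite[w2, ])
    for (child in kids) {
      if (filled >= n_children) break   # excess child discarded
      if (stats::runif(1) < cfg$child_mutation_prob)
        child <- mutate_weights(child, "gentle")
      if (any(child > cfg$domination_threshold))
        child <- mutate_weights(child, "super")
      filled <- filled + 1L
      children[filled, ] <- child
    }
  }
  for (i in seq_len(elite_n))
    if (stats::runif(1) < cfg$elite_mutation_prob)
      elite[i, ] <- mutate_weights(elite[i, ], "gentle")
  rbind(children, elite)
}

#' Run the genetic algorithm
#'
#' Executes \code{cfg$runs} independent seeded runs of
#' \code{cfg$generations} generations each and reports, per the study
#' protocol, the averaged end-of-run best/worst/mean fitness, the averaged
#' fittest weights, and the per-generation fitness history averaged over
#' runs. The single fittest organism over all runs is returned as the best.
#'
#' @param ctx a \code{"ga_context"}.
#' @param cfg a \code{"ga_config"}.
#' @return list of class \code{"ga_result"}: \code{best_weights},
#'   \code{best_fitness}, \code{avg_best_weights}, \code{avg_fitness}
#'   (named best/worst/mean), \code{history} (data frame generation, best,
#'   worst, mean averaged over runs), \code{per_run} (end-of-run summary),
#'   \code{config}.
#' @export
run_ga <- function(ctx, cfg = ga_config()) {
  stopifnot(inherits(ctx, "ga_context"), inherits(cfg, "ga_config"))
  k <- ctx$n_methods
  gens <- cfg$generations
  hist_sum <- matrix(0, max(gens, 1L), 3L)
  per_run <- matrix(NA_real_, cfg$runs, 3L,
                    dimnames = list(NULL, c("best", "worst", "mean")))
  fittest_sum <- rep(0, k)
  best_fit <- -Inf
  best_w <- rep(1 / k, k)
  for (r in seq_len(cfg$runs)) {
    set.seed(cfg$rng_seed + r - 1L)
    pop <- t(vapply(seq_len(cfg$population_size),
                    function(i) random_weights(k), numeric(k)))
    fit <- .fitness_matrix(pop, ctx, cfg$rank_threshold)
    if (gens > 0L) {
      for (g in seq_len(gens)) {
        pop <- evolve_generation(pop, fit, cfg, generation = g)
        fit <- .fitness_matrix(pop, ctx, cfg$rank_threshold)
        hist_sum[g, ] <- hist_sum[g, ] + c(max(fit), min(fit), mean(fit))
      }
    }
    per_run[r, ] <- c(max(fit), min(fit), mean(fit))
    run_best <- which.max(fit)
    fittest_sum <- fittest_sum + pop[run_best, ]
    if (fit[run_best] > best_fit) {
      best_fit <- fit[run_best]
      best_w <- pop[run_best, ]
    }
  }
  history <- if (gens > 0L)
    data.frame(generation = seq_len(gens),
               best = hist_sum[seq_len(gens), 1L] / cfg$runs,
               worst = hist_sum[seq_len(gens), 2L] / cfg$runs,
               mean = hist_sum[seq_len(gens), 3L] / cfg$runs)
  else data.frame(generation = integer(), best = numeric(),
                  worst = numeric(), mean = numeric())
  structure(list(best_weights = best_w, best_fitness = best_fit,
                 avg_best_weights = fittest_sum / cfg$runs,
                 avg_fitness = colMeans(per_run),
                 history = history, per_run = as.data.frame(per_run),
                 config = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result>", x$config$runs, "run(s) x", x$config$generations,
      "generations\n")
  cat("  best fitness:", format(x$best_fitness, digits = 4),
      " avg best fitness:", format(x$avg_fitness["best"], digits = 4), "\n")
  cat("  best weights:", paste(format(x$best_weights, digits = 4),
                               collapse = " "), "\n")
  invisible(x)
}
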