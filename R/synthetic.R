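#' Psychometric parameters for the trial generator
#'
#' The generator links discrimination performance to mixture overlap
#' through a chance-adjusted logistic: performance starts at `p_max`
#' for fully disjoint mixtures and decays towards the 3-AFC chance rate
#' as overlap approaches 100%.  Between-subject heterogeneity enters as
#' a normal horizontal shift of the midpoint.
#'
#' @param chance baseline success probability (1/3 for 3-AFC).
#' @param p_max asymptotic success probability at maximal distance.
#' @param midpoint percent overlap at which chance-corrected
#'   performance is half-maximal.
#' @param slope logistic scale in percent-overlap units (smaller is
#'   steeper).
#' @param subject_sd standard deviation of per-subject midpoint shifts,
#'   in percent-overlap units.
#' @return a list of class `psychometric_params`.
#' @export
psychometric_params <- function(chance = 1/3, p_max = 0.95, midpoint = 50,
                                slope = 8, subject_sd = 5) {
  stopifnot(chance > 0, chance < 1, p_max > chance, p_max <= 1,
            slope > 0, subject_sd >= 0)
  structure(
    list(chance = chance, p_max = p_max, midpoint = midpoint,
         slope = slope, subject_sd = subject_sd),
    class = "psychometric_params"
  )
}

#' Success probability at a given overlap
#'
#' `chance + (p_max - chance) * plogis((midpoint + offset - overlap) / slope)`;
#' decreasing in overlap, equal to `(chance + p_max) / 2` at the
#' (shifted) midpoint.
#'
#' @param params a [psychometric_params].
#' @param percent_overlap overlap of the tested pair, in `[0, 100]`;
#'   vectorized.
#' @param subject_offset horizontal midpoint shift for one subject.
#' @return success probabilities.
#' @export
success_probability <- function(params, percent_overlap,
                                subject_offset = 0) {
  stopifnot(inherits(params, "psychometric_params"),
            all(percent_overlap >= 0), all(percent_overlap <= 100))
  params$chance + (params$p_max - params$chance) *
    stats::plogis((params$midpoint + subject_offset - percent_overlap) /
                    params$slope)
}

default_overlaps <- function(N) {
  # roughly even coverage of percent overlap, excluding identical pairs
  unique(pmin(N - 1L, round(N * c(0, 0.2, 0.4, 0.6, 0.8, 0.965))))
}

#' Experimental design for the trial generator
#'
#' Defaults mirror the canonical study layout: mixtures of `N` = 10, 20
#' and 30 components from a `C` = 128 library, `T` = 20 mixture pairs
#' per overlap class, `S` = 26 subjects, each subject judging each pair
#' once.
#'
#' @param C library size.
#' @param N vector of mixture sizes.
#' @param overlaps named list of overlap counts per mixture size; by
#'   default about six classes per `N` spanning 0 to near-100% overlap.
#' @param pairs_per_class number of mixture pairs tested per class (T).
#' @param subjects number of subjects (S).
#' @return a list of class `experiment_design`.
#' @export
experiment_design <- function(C = 128, N = c(10, 20, 30), overlaps = NULL,
                              pairs_per_class = 20, subjects = 26) {
  stopifnot(all(N >= 1), all(N <= C), pairs_per_class >= 1, subjects >= 1)
  if (is.null(overlaps)) {
    overlaps <- stats::setNames(lapply(N, default_overlaps),
                                as.character(N))
  }
  for (n in N) {
    o <- overlaps[[as.character(n)]]
    if (is.null(o)) {
      stop("no overlap classes supplied for N = ", n)
    }
    if (any(o < 0 | o > n)) {
      stop("impossible overlap class for N = ", n, ": O = ",
           paste(o[o < 0 | o > n], collapse = ", "))
    }
  }
  structure(
    list(C = C, N = N, overlaps = overlaps,
         pairs_per_class = pairs_per_class, subjects = subjects),
    class = "experiment_design"
  )
}

#' Generate a synthetic trial table
#'
#' Draws one Bernoulli 3-AFC outcome per subject x mixture pair, with
#' success probability given by the psychometric link at the pair's
#' overlap and the subject's midpoint offset.  Identical
#' (design, params, seed) triples produce identical tables.
#'
#' @param design an [experiment_design].
#' @param params a [psychometric_params].
#' @param seed integer seed (mandatory: every stochastic path in this
#'   package is explicitly seeded).
#' @param materialize_components also draw explicit component sets for
#'   each pair from the `C` library (adds `mix_a`/`mix_b` list columns;
#'   off by default since the analysis only needs class labels).
#' @return a trial tibble (schema of [read_trials]) with the seed and
#'   generator parameters attached as attributes.
#' @export
generate_trials <- function(design, params = psychometric_params(),
                            seed, materialize_components = FALSE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "psychometric_params"))
  if (missing(seed)) {
    stop("generate_trials requires an explicit seed")
  }
  withr::with_seed(seed, {
    offsets <- stats::rnorm(design$subjects, 0, params$subject_sd)
    blocks <- list()
    comp_sets <- list()
    for (n in design$N) {
      for (o in design$overlaps[[as.character(n)]]) {
        pair_ids <- sprintf("N%02d_O%02d_p%02d", n, o,
                            seq_len(design$pairs_per_class))
        grid <- tidyr::expand_grid(
          subject = seq_len(design$subjects),
          pair_id = pair_ids
        )
        p <- success_probability(params, 100 * o / n,
                                 offsets[grid$subject])
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          subject_id = sprintf("s%02d", grid$subject),
          N = n, O = o, pair_id = grid$pair_id,
          correct = stats::rbinom(nrow(grid), 1, p)
        )
        if (materialize_components) {
          comp_sets[[length(comp_sets) + 1L]] <- tibble::tibble(
            pair_id = pair_ids,
            mix_a = replicate(length(pair_ids),
                              sample.int(design$C, n), simplify = FALSE),
            mix_b = lapply(seq_along(pair_ids), function(i) NULL)
          )
        }
      }
    }
    out <- dplyr::bind_rows(blocks)
    if (materialize_components) {
      comps <- dplyr::bind_rows(comp_sets)
      comps$mix_b <- lapply(seq_len(nrow(comps)), function(i) {
        a <- comps$mix_a[[i]]
        n <- length(a)
        meta <- out$O[match(comps$pair_id[i], out$pair_id)]
        shared <- if (meta > 0) sample(a, meta) else integer(0)
        pool <- setdiff(seq_len(design$C), a)
        c(shared, sample(pool, n - meta))
      })
      out <- dplyr::left_join(out, comps, by = "pair_id")
    }
    attr(out, "seed") <- seed
    attr(out, "params") <- params
    attr(out, "design") <- design
    out
  })
}

#' Resample a trial table along one axis
#'
#' Bootstrap backend: samples subjects or pairs with replacement,
#' relabelling the sampled units so the result is again a valid trial
#' table; class structure (N, O of each pair) is preserved.
#'
#' @param table a trial tibble.
#' @param axis `"subjects"` or `"pairs"`.
#' @param n number of units to draw: subjects in total, or pairs per
#'   mixture class (pairs belong to a class, so the class layout is
#'   preserved by resampling within classes).
#' @param seed integer seed.
#' @return a trial tibble with relabelled resampled units.
#' @export
resample_table <- function(table, axis = c("subjects", "pairs"), n, seed) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(table), nrow(table) > 0, n >= 1)
  if (missing(seed)) {
    stop("resample_table requires an explicit seed")
  }
  withr::with_seed(seed, {
    if (axis == "subjects") {
      units <- unique(table$subject_id)
      picks <- sample(units, n, replace = TRUE)
      out <- lapply(seq_along(picks), function(i) {
        block <- table[table$subject_id == picks[i], ]
        block$subject_id <- sprintf("%s_r%03d", picks[i], i)
        block
      })
      return(dplyr::bind_rows(out))
    }
    classes <- unique(table[, c("N", "O")])
    out <- lapply(seq_len(nrow(classes)), function(ci) {
      cls <- table[table$N == classes$N[ci] & table$O == classes$O[ci], ]
      units <- unique(cls$pair_id)
      picks <- sample(units, n, replace = TRUE)
      dplyr::bind_rows(lapply(seq_along(picks), function(i) {
        block <- cls[cls$pair_id == picks[i], ]
        block$pair_id <- sprintf("%s_r%03d", picks[i], i)
        block
      }))
    })
    dplyr::bind_rows(out)
  })
}
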