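#' Morphology generator parameters
#'
#' @param n_stems Number of primary neurites leaving the soma.
#' @param branch_prob Probability that a growing segment bifurcates at its
#'   end (before `max_depth` is reached); in `[0, 1]`.
#' @param segment_len_mean Mean segment length, um (> 0).
#' @param segment_len_sd SD of segment length, um.
#' @param max_depth Maximum segment depth per path (>= 1).
#' @param soma_radius Soma radius, um.
#' @param seed RNG seed.
#' @return An object of class `morph_gen_params`.
#' @export
morph_gen_params <- function(n_stems = 3L, branch_prob = 0.3,
                             segment_len_mean = 20, segment_len_sd = 4,
                             max_depth = 4L, soma_radius = 5, seed = NULL) {
  assert_that(max_depth >= 1L, "max_depth must be >= 1")
  assert_that(segment_len_mean > 0, "segment_len_mean must be > 0")
  assert_that(branch_prob >= 0 && branch_prob <= 1,
              "branch_prob must be in [0, 1]")
  structure(list(n_stems = as.integer(n_stems), branch_prob = branch_prob,
                 segment_len_mean = segment_len_mean,
                 segment_len_sd = segment_len_sd,
                 max_depth = as.integer(max_depth),
                 soma_radius = soma_radius, seed = seed),
            class = "morph_gen_params")
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a random branched morphology
#'
#' Grows `n_stems` neurites from a single soma node: each segment has random
#' length (truncated normal) and a direction correlated with its parent's;
#' at each segment end the path bifurcates with probability `branch_prob`.
#' Branching opportunities occur at segment depths `0 .. max_depth - 1`, so
#' with `branch_prob = 1` every path bifurcates at every opportunity, giving
#' `n_stems * 2^max_depth` terminal tips; with `branch_prob = 0` each stem is
#' an unbranched path of `max_depth + 1` segments.
#'
#' @param params A [morph_gen_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A [morphology()] object (valid SWC node table).
#' @export
generate_morphology <- function(params, seed = params$seed) {
  assert_that(inherits(params, "morph_gen_params"), "params must be morph_gen_params")
  with_seed(seed, {
    rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                            radius = params$soma_radius, parent = -1L))
    next_id <- 2L
    seg_len <- function() {
      max(0.1, stats::rnorm(1, params$segment_len_mean, params$segment_len_sd))
    }
    grow <- function(parent_id, pos, dir, depth) {
      new_pos <- pos + seg_len() * dir
      id <- next_id
      next_id <<- next_id + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, type = 3L, x = new_pos[1], y = new_pos[2], z = new_pos[3],
        radius = 0.5, parent = parent_id)
      if (depth < params$max_depth) {
        k <- if (stats::runif(1) < params$branch_prob) 2L else 1L
        for (j in seq_len(k)) {
          child_dir <- dir + 0.5 * stats::rnorm(3)
          child_dir <- child_dir / sqrt(sum(child_dir^2))
          grow(id, new_pos, child_dir, depth + 1L)
        }
      }
    }
    for (s in seq_len(params$n_stems)) {
      grow(1L, c(0, 0, 0), rand_unit(), 0L)
    }
    morphology(do.call(rbind, rows))
  })
}
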