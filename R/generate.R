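#' Specification of the synthetic onglide generator
#'
#' Describes a production experiment: speakers in two strategy groups
#' produce one utterance per target word in each accent-bearing focus
#' condition (broad, narrow, contrastive). Each utterance is a fall or a
#' rise with a group- and condition-specific fall probability; its
#' magnitude in semitones is log-normal, scaled by a per-speaker pitch-range
#' factor (itself log-normal), which right-skews the raw pooled data the
#' way real between-speaker range differences do.
#'
#' Defaults emulate the study design the analysis assumes: 27 speakers
#' (11 fall-users in group 1, 16 rise-dominant in group 2), 3 conditions,
#' 20 target words, hence 1620 accent-bearing utterances. The default fall
#' probabilities are chosen so that the pooled proportions of falls are
#' close to 47.0% / 21.9% / 9.1% for broad / narrow / contrastive focus,
#' group 1's overall fall share is near 48% (above the 1/3 grouping
#' threshold) and group 2's near 11% (below it). Rise magnitudes grow from
#' broad to contrastive focus; their default scale puts the normalised
#' modes near -0.5 and +0.5 — the region where the bimodal onglide
#' distribution is centred and where the landscape model's attractors lie
#' (around ±0.46) — so observed and model medians are directly comparable
#' in the fit.
#'
#' @param n_speakers_group1,n_speakers_group2 speakers per strategy group.
#' @param n_words target words (utterances per speaker and condition).
#' @param conditions names of the accent-bearing focus conditions.
#' @param fall_probability 2 x 3 matrix (groups x conditions) of fall
#'   probabilities.
#' @param rise_meanlog,rise_sdlog log-normal parameters of rise magnitudes
#'   (semitones), one `meanlog` per condition.
#' @param fall_meanlog,fall_sdlog log-normal parameters of fall magnitudes
#'   (absolute semitones).
#' @param speaker_range_sd sd (log scale) of the per-speaker multiplicative
#'   pitch-range factor.
#' @param include_background also emit background-condition rows, flagged
#'   unaccented (no onglide) in over 99% of cases.
#' @param exclusion_rate fraction of accent-bearing utterances dropped at
#'   random (technical failures, mispronunciations).
#' @param seed integer seed.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_speakers_group1 = 11, n_speakers_group2 = 16,
                           n_words = 20,
                           conditions = c("broad", "narrow", "contrastive"),
                           fall_probability = rbind(
                             group1 = c(0.80, 0.45, 0.19),
                             group2 = c(0.243, 0.060, 0.023)),
                           rise_meanlog = log(c(0.57, 0.65, 0.77)),
                           rise_sdlog = 0.5,
                           fall_meanlog = log(0.60), fall_sdlog = 0.5,
                           speaker_range_sd = 0.25,
                           include_background = FALSE,
                           exclusion_rate = 0, seed = 1) {
  colnames(fall_probability) <- conditions
  spec <- list(n_speakers_group1 = n_speakers_group1,
               n_speakers_group2 = n_speakers_group2,
               n_words = n_words, conditions = conditions,
               fall_probability = fall_probability,
               rise_meanlog = rise_meanlog, rise_sdlog = rise_sdlog,
               fall_meanlog = fall_meanlog, fall_sdlog = fall_sdlog,
               speaker_range_sd = speaker_range_sd,
               include_background = include_background,
               exclusion_rate = exclusion_rate, seed = seed)
  stopifnot(n_speakers_group1 >= 0, n_speakers_group2 >= 0, n_words >= 1,
            all(fall_probability >= 0), all(fall_probability <= 1),
            nrow(fall_probability) == 2,
            ncol(fall_probability) == length(conditions),
            length(rise_meanlog) == length(conditions),
            rise_sdlog > 0, fall_sdlog > 0, speaker_range_sd >= 0,
            exclusion_rate >= 0, exclusion_rate < 1)
  structure(spec, class = "generator_spec")
}

#' Generate a synthetic onglide dataset
#'
#' Draws a complete dataset from a [generator_spec()]. Falls carry negative,
#' rises positive onglides in semitones (`onglide_st`); no zeros occur. The
#' true group of each speaker is recorded in `group_true` so recovery by
#' [assign_groups()] can be checked.
#'
#' @param spec a [generator_spec()].
#' @return A data frame with columns `speaker`, `condition`, `word`,
#'   `onglide_st`, `group_true`, `accented`, and attributes `spec` and
#'   `seed`.
#' @examples
#' d <- generate_onglides(generator_spec(seed = 42))
#' nrow(d) # 27 speakers x 3 conditions x 20 words
#' @export
generate_onglides <- function(spec = generator_spec()) {
  if (!inherits(spec, "generator_spec")) stop("'spec' must be a generator_spec")
  set.seed(spec$seed)
  n_sp <- spec$n_speakers_group1 + spec$n_speakers_group2
  speakers <- sprintf("S%02d", seq_len(n_sp))
  group <- rep(c("group1", "group2"),
               c(spec$n_speakers_group1, spec$n_speakers_group2))
  range_factor <- stats::rlnorm(n_sp, 0, spec$speaker_range_sd)
  words <- sprintf("w%02d", seq_len(spec$n_words))

  d <- expand.grid(word = words, condition = spec$conditions,
                   speaker = speakers, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)[, c("speaker", "condition", "word")]
  sp_idx <- match(d$speaker, speakers)
  cond_idx <- match(d$condition, spec$conditions)
  p_fall <- spec$fall_probability[cbind(match(group[sp_idx], rownames(spec$fall_probability)),
                                        cond_idx)]
  is_fall <- stats::runif(nrow(d)) < p_fall
  mag <- ifelse(is_fall,
                stats::rlnorm(nrow(d), spec$fall_meanlog, spec$fall_sdlog),
                stats::rlnorm(nrow(d), spec$rise_meanlog[cond_idx],
                              spec$rise_sdlog))
  d$onglide_st <- ifelse(is_fall, -1, 1) * mag * range_factor[sp_idx]
  d$group_true <- group[sp_idx]
  d$accented <- TRUE

  if (spec$exclusion_rate > 0)
    d <- d[stats::runif(nrow(d)) >= spec$exclusion_rate, , drop = FALSE]

  if (spec$include_background) {
    bg <- expand.grid(word = words, condition = "background",
                      speaker = speakers, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("speaker", "condition", "word")]
    bg$onglide_st <- NA_real_
    bg$group_true <- group[match(bg$speaker, speakers)]
    # over 99% of background productions lack a nuclear accent on the target
    bg$accented <- stats::runif(nrow(bg)) < 0.005
    bg$onglide_st[bg$accented] <-
      stats::rlnorm(sum(bg$accented), spec$rise_meanlog[1], spec$rise_sdlog)
    d <- rbind(d, bg)
  }
  rownames(d) <- NULL
  attr(d, "spec") <- spec
  attr(d, "seed") <- spec$seed
  d
}

#' Generate onglides directly from the landscape model
#'
#' For each condition, final states of the stochastic landscape system at
#' that condition's tilt become normalised onglides — data whose generating
#' tilt is known exactly, for end-to-end self-consistency checks of the
#' fitting pipeline.
#'
#' @param k_per_condition named numeric vector of tilts, e.g.
#'   `c(broad = 0.3, narrow = 3.3, contrastive = 5.4)`.
#' @param n_per_condition runs (utterances) per condition.
#' @param sigma,dt,n_steps,init simulation settings, as in
#'   [simulate.landscape()].
#' @param seed integer seed.
#' @return A data frame with `condition`, `onglide_norm`, and attribute
#'   `k_per_condition`. Exact zeros (measure-zero in theory, possible in
#'   floating point) are dropped.
#' @export
generate_from_model <- function(k_per_condition, n_per_condition = 2500,
                                sigma = 1, dt = 0.005, n_steps = 2000,
                                init = c(-1, 1), seed = 1) {
  stopifnot(length(k_per_condition) >= 1, !is.null(names(k_per_condition)))
  out <- lapply(seq_along(k_per_condition), function(i) {
    x <- simulate(landscape("cubic_tilt", k_per_condition[i], sigma),
                  nsim = n_per_condition, seed = seed + i, dt = dt,
                  n_steps = n_steps, init = init)
    data.frame(condition = names(k_per_condition)[i], onglide_norm = x)
  })
  d <- do.call(rbind, out)
  d <- d[d$onglide_norm != 0, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "k_per_condition") <- k_per_condition
  d
}

#' Read / write onglide datasets as delimited text
#'
#' CSV with header; columns `speaker`, `condition`, `word`, `onglide_st`
#' and optionally `onglide_norm`, `group`, `accented`. A column-mapping
#' argument adapts files with other column names. Round-trips are lossless
#' to full double precision (values are written with 17 significant
#' digits).
#'
#' @param path file path.
#' @param col_map named character vector mapping standard names to the
#'   file's names, e.g. `c(onglide_st = "onglide")`.
#' @return `read_onglides()` returns the data frame; `write_onglides()`
#'   returns `path` invisibly.
#' @export
read_onglides <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map)) {
      i <- match(col_map[[std]], names(d))
      if (is.na(i)) stop("mapped column not found in file: ", col_map[[std]])
      names(d)[i] <- std
    }
  need <- c("speaker", "condition", "word", "onglide_st")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"accented" %in% names(d))
    d$accented <- d$condition != "background"
  known <- c("background", "broad", "narrow", "contrastive")
  bad <- setdiff(unique(d$condition), known)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  zero <- which(d$accented & !is.na(d$onglide_st) & d$onglide_st == 0)
  if (length(zero))
    stop("zero onglide at line ", zero[1] + 1L,
         ": a zero onglide is neither falling nor rising")
  d
}

#' @rdname read_onglides
#' @param data data frame of onglide records.
#' @export
write_onglides <- function(data, path) {
  stopifnot(is.data.frame(data))
  num <- vapply(data, is.numeric, logical(1))
  out <- data
  out[num] <- lapply(data[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
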