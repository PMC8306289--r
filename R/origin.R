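#' Classify ASV origin for one experimental group
#'
#' The engraftment-tracking scheme: within a group, an ASV is
#' * `human_only` if it is detected in the donor (FMT input) material and in
#'   none of the group's baseline (T0) recipient samples,
#' * `mouse_only` if it is detected at baseline in any mouse of the group
#'   and not in the donor,
#' * `shared` if detected in both — shared ASVs are counted with the human
#'   class downstream, on the rationale that foreign bacteria thrive where
#'   similar organisms already persist,
#' * `unassigned` if it appears only at post-baseline timepoints (an
#'   explicit residual class for de-novo ASVs keeps niche fractions
#'   summing to one).
#'
#' Presence in the donor community means detection in ANY donor replicate
#' (replicates are technical). Origin is group-specific: the same ASV may be
#' `mouse_only` in one group and `unassigned` in another, because the
#' baseline rule is "identified in any mouse from a group at baseline".
#'
#' @param table a [count_table()].
#' @param metadata validated metadata (see [read_metadata()]).
#' @param group group label, e.g. `"G3"`.
#' @param min_count detection threshold in reads (default 1, i.e. any
#'   nonzero count counts as "identified").
#' @return An `origin_map` data.frame with columns `asv_id`, `origin`
#'   (`human_only`/`shared`/`mouse_only`/`unassigned`), `class`
#'   (`human`/`mouse`/`unassigned`), restricted to ASVs observed in the
#'   group's or donor samples; attributes `group` and `min_count`.
#' @export
classify_origin <- function(table, metadata, group, min_count = 1) {
  metadata <- validate_metadata(metadata)
  donor_ids <- donor_sample_ids(metadata)
  if (!length(donor_ids)) stop("no donor samples in metadata", call. = FALSE)
  t0_ids <- group_sample_ids(metadata, group, "T0")
  if (!length(t0_ids)) {
    stop("no baseline (T0) samples for group ", group, call. = FALSE)
  }
  group_ids <- group_sample_ids(metadata, group)
  check_samples_present(table, c(donor_ids, group_ids))
  m <- unclass(as.matrix(table))

  detected <- function(ids) {
    apply(m[ids, , drop = FALSE] >= min_count, 2, any)
  }
  in_donor <- detected(donor_ids)
  in_t0 <- detected(t0_ids)
  observed <- detected(c(donor_ids, group_ids))

  origin <- ifelse(in_donor & in_t0, "shared",
            ifelse(in_donor, "human_only",
            ifelse(in_t0, "mouse_only", "unassigned")))
  keep <- observed
  map <- data.frame(asv_id = colnames(m)[keep],
                    origin = origin[keep],
                    stringsAsFactors = FALSE)
  map$class <- c(human_only = "human", shared = "human",
                 mouse_only = "mouse", unassigned = "unassigned")[map$origin]
  structure(map, group = group, min_count = min_count,
            class = c("origin_map", "data.frame"))
}

#' ASVs uniquely identified in the donor input material
#'
#' @param origin_map output of [classify_origin()].
#' @return Character vector of the `human_only` ASV ids.
#' @export
unique_input_asvs <- function(origin_map) {
  origin_map$asv_id[origin_map$origin == "human_only"]
}

#' Niche-occupancy time series by origin class
#'
#' For each recipient sample of the map's group, the fraction of the niche
#' occupied by each origin class: the sum of the sample's relative
#' abundances over the ASVs of that class. Fractions over
#' `{human, mouse, unassigned}` sum to one per sample. Group summaries are
#' the mean and sample standard deviation (denominator `n - 1`) over the
#' mice at each timepoint.
#'
#' @param table a [count_table()].
#' @param metadata validated metadata.
#' @param origin_map output of [classify_origin()] for the group of
#'   interest.
#' @param by `"class"` (default: human/mouse/unassigned) or `"origin"`
#'   (human_only/shared/mouse_only/unassigned granularity).
#' @return An `occupancy_series` list: `group`; `fractions` (long
#'   data.frame: `sample_id`, `subject_id`, `timepoint`, `class`,
#'   `fraction`); `summary` (`timepoint`, `class`, `mean`, `sd`, `n`).
#' @export
occupancy_series <- function(table, metadata, origin_map,
                             by = c("class", "origin")) {
  by <- match.arg(by)
  metadata <- validate_metadata(metadata)
  group <- attr(origin_map, "group")
  ids <- group_sample_ids(metadata, group)
  if (!length(ids)) stop("no recipient samples for group ", group, call. = FALSE)
  check_samples_present(table, ids)
  prop <- relative_abundance(unclass(as.matrix(table))[ids, , drop = FALSE])

  levels_by <- if (by == "class") c("human", "mouse", "unassigned") else
    c("human_only", "shared", "mouse_only", "unassigned")
  labels <- origin_map[[if (by == "class") "class" else "origin"]]
  frac <- vapply(levels_by, function(cl) {
    asvs <- intersect(origin_map$asv_id[labels == cl], colnames(prop))
    rowSums(prop[, asvs, drop = FALSE])
  }, numeric(nrow(prop)))
  if (nrow(prop) == 1) {
    frac <- matrix(frac, nrow = 1, dimnames = list(rownames(prop), levels_by))
  }
  # ASVs never seen in this group's or donor samples are outside the map;
  # their (zero-count) columns contribute nothing, but any residual mass
  # from unmapped ASVs is counted as unassigned to preserve the sum-to-one
  # contract.
  residual <- 1 - rowSums(frac)
  frac[, "unassigned"] <- frac[, "unassigned"] + pmax(residual, 0)

  md <- metadata[match(rownames(frac), metadata$sample_id), ]
  fractions <- data.frame(
    sample_id = rep(rownames(frac), times = length(levels_by)),
    subject_id = rep(md$subject_id, times = length(levels_by)),
    timepoint = rep(md$timepoint, times = length(levels_by)),
    class = rep(levels_by, each = nrow(frac)),
    fraction = as.vector(frac),
    stringsAsFactors = FALSE
  )
  summary_df <- do.call(rbind, lapply(split(
    fractions, list(fractions$timepoint, fractions$class)), function(sub) {
      if (!nrow(sub)) return(NULL)
      data.frame(timepoint = sub$timepoint[1], class = sub$class[1],
                 mean = mean(sub$fraction),
                 sd = if (nrow(sub) > 1) stats::sd(sub$fraction) else NA_real_,
                 n = nrow(sub), stringsAsFactors = FALSE)
    }))
  summary_df <- summary_df[order(summary_df$timepoint, summary_df$class), ]
  rownames(summary_df) <- NULL
  structure(list(group = group, by = by, fractions = fractions,
                 summary = summary_df),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("Niche occupancy for group %s (%s level)\n", x$group, x$by))
  print(utils::head(x$summary, 12))
  invisible(x)
}

#' Test human-vs-mouse niche occupancy after FMT
#'
#' One one-sided paired Wilcoxon signed-rank test per (group, timepoint),
#' pairing the human-class and mouse-class fractions within each mouse,
#' with the alternative that human-derived ASVs occupy more of the niche
#' than mouse ASVs. Benjamini-Hochberg adjustment is applied across the
#' full family of tests in the invocation (all groups x timepoints passed
#' in), mirroring per-timepoint figure annotations.
#'
#' @param series an `occupancy_series` (class level) or list of them, one
#'   per group.
#' @param timepoints timepoints to test (default `T3`, `T4`, `T5`, the
#'   post-FMT weeks).
#' @return data.frame: `group`, `timepoint`, `n_pairs`, `statistic`, `p`,
#'   `p_adjusted`, `exact`. Timepoints absent for a group are skipped with
#'   a warning.
#' @export
compare_human_vs_mouse <- function(series, timepoints = c("T3", "T4", "T5")) {
  if (inherits(series, "occupancy_series")) series <- list(series)
  rows <- list()
  for (s in series) {
    if (!identical(s$by, "class")) {
      stop("occupancy series must be at class granularity", call. = FALSE)
    }
    fr <- s$fractions
    for (tp in timepoints) {
      sub <- fr[fr$timepoint == tp, ]
      if (!nrow(sub)) {
        warning("group ", s$group, ": timepoint ", tp, " missing; skipped")
        next
      }
      wide <- merge(sub[sub$class == "human", c("subject_id", "fraction")],
                    sub[sub$class == "mouse", c("subject_id", "fraction")],
                    by = "subject_id", suffixes = c("_human", "_mouse"))
      if (nrow(wide) < 2) {
        warning("group ", s$group, ": timepoint ", tp,
                " has < 2 paired subjects; skipped")
        next
      }
      t <- wilcoxon_signed_rank(wide$fraction_human, wide$fraction_mouse,
                                alternative = "greater")
      rows[[length(rows) + 1]] <- data.frame(
        group = s$group, timepoint = tp, n_pairs = t$n_pairs,
        statistic = t$statistic, p = t$p, exact = t$exact,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out[, c("group", "timepoint", "n_pairs", "statistic", "p", "p_adjusted",
          "exact")]
}
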