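#' Modality and criterion vocabularies of the reader study
#'
#' Five panoramic modalities (conventional PAN baseline, virtual
#' monoenergetic images at 40 and 60 keV, the bone PETI alone, and the
#' bone + soft-tissue PETI combination) rated on five ordinal criteria.
#'
#' @return Character vector of valid levels.
#' @export
score_modalities <- function() c("PAN", "PVMI40", "PVMI60", "PETI_BONE", "PETI_COMBO")

#' @rdname score_modalities
#' @export
score_criteria <- function() c("bone_quality", "detail_visualization",
                               "artefacts", "overall_quality",
                               "diagnostic_acceptability")

#' Validate a long-format reader score table
#'
#' @param df Data frame with columns `reader`, `case`, `modality`,
#'   `criterion`, `score` (integer 1-5).
#' @return The validated data frame with class `score_table`.
#' @export
score_table <- function(df) {
  need <- c("reader", "case", "modality", "criterion", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad <- which(!(df$score %in% 1:5))
  if (length(bad))
    stop("invalid score (must be an integer 1-5) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  badm <- setdiff(unique(df$modality), score_modalities())
  if (length(badm)) stop("unknown modality: ", paste(badm, collapse = ", "))
  badc <- setdiff(unique(df$criterion), score_criteria())
  if (length(badc)) stop("unknown criterion: ", paste(badc, collapse = ", "))
  key <- paste(df$reader, df$case, df$modality, df$criterion, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (reader, case, modality, criterion) key in row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  df$score <- as.integer(df$score)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Load reader scores from CSV
#'
#' @param path CSV with columns `reader`, `case`, `modality`, `criterion`,
#'   `score`.
#' @return A validated `score_table` data frame.
#' @export
load_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  score_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Across-reader average of per-reader mean scores
#'
#' The unweighted mean of the per-reader means (all readers rate the same
#' cases, so case counts are equal), rounded to `digits` decimals as
#' reported.
#'
#' @param reader_means Numeric vector of per-reader mean scores.
#' @param digits Decimals for reporting (default 2).
#' @return Scalar average score.
#' @export
across_reader_average <- function(reader_means, digits = 2) {
  round(mean(reader_means), digits)
}

#' Aggregate reader scores
#'
#' Per (modality, criterion): each reader's mean and standard deviation, and
#' the across-reader average (unweighted mean of reader means). Per
#' modality: total points, the sum of all per-reader means over the
#' criteria (maximum `5 * criteria * readers`).
#'
#' @param tbl A `score_table`.
#' @return List with `by_reader` (modality, criterion, reader, mean, sd),
#'   `summary` (modality, criterion, average), and `totals` (modality,
#'   total_points).
#' @export
aggregate_scores <- function(tbl) {
  tbl <- score_table(tbl)
  if (!nrow(tbl)) stop("empty score table")
  by_reader <- stats::aggregate(score ~ modality + criterion + reader,
                                data = tbl,
                                FUN = function(s) c(mean = mean(s), sd = stats::sd(s)))
  by_reader <- data.frame(by_reader[c("modality", "criterion", "reader")],
                          mean = by_reader$score[, "mean"],
                          sd = by_reader$score[, "sd"])
  summary <- stats::aggregate(mean ~ modality + criterion, data = by_reader,
                              FUN = function(m) across_reader_average(m))
  names(summary)[names(summary) == "mean"] <- "average"
  totals <- stats::aggregate(mean ~ modality, data = by_reader, FUN = sum)
  names(totals)[names(totals) == "mean"] <- "total_points"
  mo <- intersect(score_modalities(), unique(tbl$modality))
  co <- intersect(score_criteria(), unique(tbl$criterion))
  by_reader <- by_reader[order(match(by_reader$modality, mo),
                               match(by_reader$criterion, co),
                               by_reader$reader), ]
  summary <- summary[order(match(summary$modality, mo),
                           match(summary$criterion, co)), ]
  totals <- totals[order(match(totals$modality, mo)), ]
  rownames(by_reader) <- rownames(summary) <- rownames(totals) <- NULL
  list(by_reader = by_reader, summary = summary, totals = totals)
}

#' Wilcoxon signed-rank test for paired ordinal scores
#'
#' Classical zero-discard convention: differences `d = x - y`, zeros removed
#' (n adjusted), mid-ranks of `|d|` for ties, `W = min(W+, W-)`. The
#' two-sided p-value is exact — computed by enumerating the distribution of
#' W+ over all `2^n` equiprobable sign assignments of the observed (possibly
#' tied, mid-ranked) rank vector — when `n <= exact_max_n`; for larger n a
#' normal approximation with tie correction and continuity correction is
#' used, matching common statistical-software defaults.
#'
#' @param x,y Equal-length paired score vectors.
#' @param exact_max_n Largest n for the exact p-value (default 15).
#' @return A `wilcoxon_result`: list with `statistic` (W), `w_plus`,
#'   `w_minus`, `p_value`, `n` (after zero removal), `direction` (sign of
#'   the median difference), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 15) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("no nonzero pairs: all differences are zero, test undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max_n) {
    # exact null distribution of W+ over the 2^n sign assignments of the
    # observed rank vector (valid with mid-ranked ties)
    masks <- 0:(2^n - 1)
    bits <- vapply(seq_len(n), function(i)
      bitwAnd(bitwShiftR(masks, i - 1L), 1L), integer(length(masks)))
    wdist <- as.vector(bits %*% r)
    p <- min(1, 2 * mean(wdist <= w + 1e-9))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie and continuity corrected)"
  }
  structure(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                 p_value = p, n = n,
                 direction = sign(stats::median(d)), method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s), %s\n",
              x$statistic, x$n, x$p_value, x$method,
              c("median diff < 0", "no median diff", "median diff > 0")[x$direction + 2]))
  invisible(x)
}

#' Compare every modality against a baseline, per criterion
#'
#' Pairs scores by (reader, case) and runs [wilcoxon_signed_rank()] for each
#' non-baseline modality and criterion. Comparisons where all paired
#' differences are zero are reported with status `"untestable"` rather than
#' a p-value. Keys present for only one of the two modalities are an error.
#'
#' @param tbl A `score_table`.
#' @param baseline Baseline modality (default `"PAN"`).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) mirrors reporting without
#'   multiplicity correction.
#' @return Data frame: modality, criterion, n, statistic, p_value,
#'   direction, significant, status.
#' @export
compare_modalities <- function(tbl, baseline = "PAN", alpha = 0.05,
                               p_adjust = "none") {
  tbl <- score_table(tbl)
  if (!baseline %in% tbl$modality)
    stop("baseline modality '", baseline, "' not present in table")
  others <- setdiff(intersect(score_modalities(), unique(tbl$modality)),
                    baseline)
  crits <- intersect(score_criteria(), unique(tbl$criterion))
  rows <- list()
  for (m in others) for (cr in crits) {
    a <- tbl[tbl$modality == m & tbl$criterion == cr, ]
    b <- tbl[tbl$modality == baseline & tbl$criterion == cr, ]
    ka <- paste(a$reader, a$case, sep = "\r")
    kb <- paste(b$reader, b$case, sep = "\r")
    only <- c(setdiff(ka, kb), setdiff(kb, ka))
    if (length(only))
      stop("unpaired (reader, case) keys for ", m, " vs ", baseline, " [",
           cr, "]: ", paste(gsub("\r", "/", utils::head(only, 5)),
                            collapse = ", "))
    b <- b[match(ka, kb), ]
    res <- tryCatch(wilcoxon_signed_rank(a$score, b$score),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        modality = m, criterion = cr, n = 0L, statistic = NA_real_,
        p_value = NA_real_, direction = 0, significant = FALSE,
        status = "untestable")
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        modality = m, criterion = cr, n = res$n, statistic = res$statistic,
        p_value = res$p_value, direction = res$direction,
        significant = NA, status = "ok")
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  ok <- out$status == "ok"
  out$p_value[ok] <- stats::p.adjust(out$p_value[ok], method = p_adjust)
  out$significant <- ok & !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Simulate a reader score table
#'
#' Draws baseline ordinal scores per (reader, case, criterion) from a
#' categorical distribution over 1..5 and derives each modality's score from
#' the same draw by an ordinal shift (clipped to 1..5). This mirrors the
#' paired design: modalities rated on the same cases by the same readers,
#' differing by a systematic quality offset.
#'
#' @param n_readers,n_cases Study size (defaults 3 readers, 17 cases).
#' @param base_probs Probabilities of scores 1..5 for the baseline draw.
#' @param shift Named integer vector of per-modality ordinal shifts relative
#'   to the baseline draw (modalities absent from `shift` are omitted from
#'   the table).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `score_table`.
#' @export
simulate_score_table <- function(n_readers = 3, n_cases = 17,
                                 base_probs = c(0.05, 0.15, 0.35, 0.30, 0.15),
                                 shift = c(PAN = 0L, PVMI40 = 0L, PVMI60 = 0L,
                                           PETI_BONE = 1L, PETI_COMBO = 1L),
                                 seed = 1L) {
  stopifnot(length(base_probs) == 5, all(base_probs >= 0), sum(base_probs) > 0)
  if (!all(names(shift) %in% score_modalities()))
    stop("shift names must be valid modalities")
  grid <- expand.grid(reader = paste0("R", seq_len(n_readers)),
                      case = paste0("C", seq_len(n_cases)),
                      criterion = score_criteria(),
                      stringsAsFactors = FALSE)
  base <- with_local_seed(seed,
    sample.int(5, nrow(grid), replace = TRUE, prob = base_probs / sum(base_probs)))
  rows <- lapply(names(shift), function(m) {
    g <- grid
    g$modality <- m
    g$score <- pmin(5L, pmax(1L, base + shift[[m]]))
    g
  })
  score_table(do.call(rbind, rows))
}

#' Format comparison results as a report table
#'
#' Text table mirroring the reader-study layout: one block per modality with
#' per-reader means, across-reader average, and the p-value against the
#' baseline.
#'
#' @param agg Result of [aggregate_scores()].
#' @param cmp Result of [compare_modalities()] (optional).
#' @param baseline Baseline modality label.
#' @return Character vector of report lines (also printed invisibly usable
#'   with `writeLines()`).
#' @export
format_report <- function(agg, cmp = NULL, baseline = "PAN") {
  lines <- character(0)
  for (m in unique(agg$summary$modality)) {
    tot <- agg$totals$total_points[agg$totals$modality == m]
    lines <- c(lines, sprintf("%s (%.0f points)", m, round(tot)))
    for (cr in agg$summary$criterion[agg$summary$modality == m]) {
      br <- agg$by_reader[agg$by_reader$modality == m &
                            agg$by_reader$criterion == cr, ]
      avg <- agg$summary$average[agg$summary$modality == m &
                                   agg$summary$criterion == cr]
      pv <- ""
      if (!is.null(cmp) && m != baseline) {
        row <- cmp[cmp$modality == m & cmp$criterion == cr, ]
        if (nrow(row) == 1)
          pv <- if (row$status == "ok")
            sprintf("  p=%s", format.pval(row$p_value, digits = 2)) else "  (untestable)"
      }
      lines <- c(lines, sprintf("  %-26s %s  avg %.2f%s", cr,
                                paste(sprintf("%.2f+-%.2f", br$mean, br$sd),
                                      collapse = "  "), avg, pv))
    }
  }
  lines
}
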