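#' Hybridization spot density of a gene in a delineated region
#'
#' Counts the gene's spots inside (or on the boundary of) the polygon -
#' even-odd rule, boundary inclusive - and reports the density in spots per
#' 100 square micrometres, the unit used for within-gene comparisons of
#' hybridization signal between stages.
#'
#' @param spots a \code{\link{spot_table}}
#' @param region a \code{\link{polygon_region}}
#' @param gene gene id to count
#' @param section_id optional section filter
#' @return one-row data.frame: \code{gene_id}, \code{section_id},
#'   \code{region}, \code{count}, \code{area}, \code{density}
#' @export
spot_density <- function(spots, region, gene, section_id = NULL) {
  stopifnot(inherits(region, "polygon_region"))
  s <- spots[spots$gene_id == gene, , drop = FALSE]
  if (!is.null(section_id) && "section_id" %in% names(s))
    s <- s[s$section_id == section_id, , drop = FALSE]
  cnt <- if (nrow(s)) sum(point_in_polygon(s$x, s$y, region$vertices)) else 0L
  data.frame(gene_id = gene,
             section_id = if (is.null(section_id)) NA_character_ else section_id,
             region = region$name,
             count = as.integer(cnt),
             area = region$area,
             density = cnt / region$area * 100,
             stringsAsFactors = FALSE)
}

#' Between-stage comparison of spot densities for one gene
#'
#' Sections from the same spike are technical replicates: their densities
#' are averaged first, so the test runs on one value per spike (the
#' biological replicate). Stages are then compared with a two-sided Welch
#' t-test on the per-spike densities, and the fold change is the ratio of
#' stage means in the order given by \code{stage_order} (defaults to sorted
#' stage labels). A zero denominator yields an infinite fold change with a
#' flag, never an error; a stage with fewer than 2 spikes yields a missing
#' p-value but still reports the fold change.
#'
#' @param records data.frame with columns \code{density}, \code{stage},
#'   \code{spike_id} (biological replicate) and optionally
#'   \code{section_id}; typically rows of \code{\link{spot_density}} output
#'   augmented with the replicate structure
#' @param stage_order length-2 character vector fixing the fold-change
#'   orientation (stage1 over stage2)
#' @return list: \code{stages}, \code{spike_means} (named list per stage),
#'   \code{fold_change}, \code{p}, \code{t}, \code{df}, \code{flag}
#' @export
compare_stage_density <- function(records, stage_order = NULL) {
  stopifnot(all(c("density", "stage", "spike_id") %in% names(records)))
  stages <- if (is.null(stage_order)) sort(unique(as.character(records$stage)))
            else stage_order
  if (length(stages) != 2) stop("exactly two stages are required")
  per_spike <- lapply(stages, function(st) {
    r <- records[records$stage == st, , drop = FALSE]
    vapply(split(r$density, r$spike_id), mean, 0)   # technical reps averaged
  })
  names(per_spike) <- stages
  m1 <- mean(per_spike[[1]]); m2 <- mean(per_spike[[2]])
  flag <- NULL
  fc <- if (m2 == 0) { flag <- "zero-denominator"; Inf * sign(m1 + (m1 == 0)) } else m1 / m2
  if (m1 == 0 && m2 == 0) fc <- NaN
  if (length(per_spike[[1]]) >= 2 && length(per_spike[[2]]) >= 2 &&
      (stats::sd(per_spike[[1]]) > 0 || stats::sd(per_spike[[2]]) > 0)) {
    tt <- stats::t.test(per_spike[[1]], per_spike[[2]], var.equal = FALSE)
    p <- tt$p.value; tstat <- unname(tt$statistic); df <- unname(tt$parameter)
  } else if (length(per_spike[[1]]) >= 2 && length(per_spike[[2]]) >= 2) {
    # all values identical in both stages: no variance, no evidence
    p <- 1; tstat <- 0; df <- NA_real_
  } else {
    flag <- c(flag, "insufficient-replicates")
    p <- NA_real_; tstat <- NA_real_; df <- NA_real_
  }
  list(stages = stages, spike_means = per_spike, fold_change = fc,
       p = p, t = tstat, df = df, flag = flag)
}

#' Assign each gene to the spike region where it is most highly expressed
#'
#' One-way layout per gene over the (typically three) spike regions using
#' the replicate-level normalized expression, followed by Tukey's HSD. The
#' winning region is the one with the largest mean, accepted only when its
#' Tukey contrast against the runner-up region is significant at
#' \code{alpha} (set \code{strict = TRUE} to require significance against
#' every other region). Degenerate tables with zero within-region variance
#' but unequal means are assigned with p reported as 0 and flagged.
#'
#' @param table a \code{\link{region_table}}
#' @param alpha significance level (default 0.05)
#' @param strict require the winner to beat all other regions, not just the
#'   runner-up
#' @return data.frame of class \code{region_assignment}: \code{gene_id},
#'   \code{winner} (NA = none), \code{p_runner_up}, \code{flag}
#' @export
region_assignment <- function(table, alpha = 0.05, strict = FALSE) {
  stopifnot(all(c("gene_id", "region", "replicate", "value") %in% names(table)))
  genes <- unique(table$gene_id)
  out <- lapply(genes, function(g) {
    d <- table[table$gene_id == g, , drop = FALSE]
    d$region <- factor(d$region)
    if (any(tapply(d$value, d$region, length) < 2))
      stop("gene ", g, ": fewer than 2 replicates in a region")
    means <- tapply(d$value, d$region, mean)
    ord <- order(means, decreasing = TRUE)
    top <- names(means)[ord[1]]
    others <- if (strict) names(means)[ord[-1]] else names(means)[ord[2]]
    if (all(means == means[1]))
      return(data.frame(gene_id = g, winner = NA_character_,
                        p_runner_up = NA_real_, flag = NA_character_,
                        stringsAsFactors = FALSE))
    wvar <- sum(tapply(d$value, d$region, function(v) sum((v - mean(v))^2)))
    if (wvar <= .Machine$double.eps * sum(d$value^2))
      return(data.frame(gene_id = g, winner = top, p_runner_up = 0,
                        flag = "degenerate-zero-variance",
                        stringsAsFactors = FALSE))
    fit <- stats::aov(value ~ region, data = d)
    tk <- stats::TukeyHSD(fit)$region
    pair_p <- function(a, b) {
      key1 <- paste(a, b, sep = "-"); key2 <- paste(b, a, sep = "-")
      if (key1 %in% rownames(tk)) tk[key1, "p adj"] else tk[key2, "p adj"]
    }
    ps <- vapply(others, function(o) pair_p(top, o), 0)
    win <- if (all(ps < alpha)) top else NA_character_
    data.frame(gene_id = g, winner = win, p_runner_up = max(ps),
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("region_assignment", class(out))
  out
}

#' Chi-square test for regional enrichment of a cluster's markers
#'
#' Counts how many of a cluster's marker genes win each spike region (per
#' \code{\link{region_assignment}}; genes without a winner are excluded) and
#' tests the counts against a uniform distribution over regions with a
#' chi-square goodness-of-fit test (df = regions - 1). Fewer than 5
#' assigned genes triggers a small-count flag on the reported p-value.
#'
#' @param markers character vector of the cluster's marker gene ids
#' @param assignments \code{region_assignment} table
#' @param regions region names defining the count vector order; defaults to
#'   the regions appearing in \code{assignments}
#' @return list: \code{counts} (named), \code{statistic}, \code{df},
#'   \code{p}, \code{n_assigned}, \code{flag}
#' @export
region_enrichment <- function(markers, assignments, regions = NULL) {
  stopifnot(inherits(assignments, "data.frame"))
  if (is.null(regions)) {
    regions <- sort(unique(assignments$winner[!is.na(assignments$winner)]))
  }
  a <- assignments[assignments$gene_id %in% markers & !is.na(assignments$winner), ]
  counts <- table(factor(a$winner, levels = regions))
  counts <- stats::setNames(as.integer(counts), regions)
  n <- sum(counts)
  if (n == 0)
    return(list(counts = counts, statistic = NA_real_,
                df = length(regions) - 1L, p = NA_real_,
                n_assigned = 0L, flag = "no-assigned-genes"))
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(counts = counts, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value,
       n_assigned = n,
       flag = if (n < 5) "small-count" else NULL)
}
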