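#' Gene regulation variation (GRV) between two consecutive comparisons
#'
#' For one GO category with `D1`/`U1` down- and up-regulated genes in the
#' first phase comparison and `D2`/`U2` in the second,
#' `GRV = ((D1 - D2) + (U2 - U1)) / (D1 + D2 + U1 + U2)`.
#' It ranges over \[-1, 1\] and reaches 1 when a category flips from all-down
#' to all-up across the transition. A zero denominator yields `NA` (the
#' category is absent from both comparisons), not an error.
#'
#' Vectorised over all four arguments.
#'
#' @param d1,u1 down/up gene counts in the first comparison.
#' @param d2,u2 down/up gene counts in the second comparison.
#' @return numeric vector in \[-1, 1\], `NA` where all four counts are zero.
#' @examples
#' grv(39, 0, 1, 51)  # 89/91, the ATPase-activity worked example
#' @export
grv <- function(d1, u1, d2, u2) {
  stopifnot(all(c(d1, u1, d2, u2) >= 0))
  s <- d1 + d2 + u1 + u2
  ifelse(s == 0, NA_real_, ((d1 - d2) + (u2 - u1)) / s)
}

#' Gene number variation (GNV) between two consecutive comparisons
#'
#' `GNV = ((D2 + U2) - (D1 + U1)) / (D1 + D2 + U1 + U2)`: the normalised
#' change in how many genes of the category are differentially expressed at
#' all, regardless of direction. Range \[-1, 1\]; `NA` on a zero denominator.
#'
#' @inheritParams grv
#' @return numeric vector in \[-1, 1\], `NA` where all four counts are zero.
#' @examples
#' gnv(39, 0, 2, 79)  # 42/120 = 0.35, microtubule-based movement
#' @export
gnv <- function(d1, u1, d2, u2) {
  stopifnot(all(c(d1, u1, d2, u2) >= 0))
  s <- d1 + d2 + u1 + u2
  ifelse(s == 0, NA_real_, ((d2 + u2) - (d1 + u1)) / s)
}

#' Tally up/down consensus calls per GO category and comparison
#'
#' For every GO term in the annotation map and every comparison present in
#' the consensus table, counts the member genes called down (`D`) and up
#' (`U`). Genes annotated to several terms count once per term; genes absent
#' from the map are ignored. Terms with no differentially expressed member
#' are kept with `D = U = 0` so that downstream dynamics can report them.
#'
#' @param consensus data.frame from [consensus_table()].
#' @param go_map data.frame with columns `gene_id`, `go_code`, `go_name`,
#'   `go_domain` (see [read_go_map()]).
#' @return data.frame with columns `go_code`, `go_name`, `go_domain`,
#'   `comparison`, `D`, `U`.
#' @export
tally_categories <- function(consensus, go_map) {
  if (NROW(go_map) == 0) stop("empty annotation map")
  go_map <- unique(go_map[, c("gene_id", "go_code", "go_name", "go_domain")])
  terms <- unique(go_map[, c("go_code", "go_name", "go_domain")])
  comparisons <- unique(consensus$comparison)
  grid <- merge(terms, data.frame(comparison = comparisons))
  de <- consensus[consensus$status != "ns", ]
  m <- merge(de, go_map, by = "gene_id")
  if (nrow(m)) {
    key <- paste(m$go_code, m$comparison, sep = "\r")
    d <- rowsum((m$status == "down") + 0L, key)
    u <- rowsum((m$status == "up") + 0L, key)
    gkey <- paste(grid$go_code, grid$comparison, sep = "\r")
    idx <- match(gkey, rownames(d))
    grid$D <- ifelse(is.na(idx), 0L, as.integer(d[idx, 1]))
    grid$U <- ifelse(is.na(idx), 0L, as.integer(u[idx, 1]))
  } else {
    grid$D <- 0L
    grid$U <- 0L
  }
  grid <- grid[order(grid$go_code, match(grid$comparison, comparisons)), ]
  rownames(grid) <- NULL
  grid
}

#' GRV/GNV dynamics over consecutive comparison pairs
#'
#' Evaluates [grv()] and [gnv()] for every GO category over each ordered pair
#' of consecutive comparisons (by default the pairs
#' (preTO vs MC, TO vs preTO) and (TO vs preTO, MC vs TO), following the
#' temporal succession of the cycle) and flags the high-change categories.
#' Under the default `rule = "or"` a category is selected when
#' `|GRV| > tau` or `|GNV| > tau`; `rule = "and"` requires both. Categories
#' absent from both comparisons carry `NA` metrics and are never selected.
#' The result is sorted by the total number of involved genes
#' `D1 + U1 + D2 + U2`, descending — the "most represented" ordering.
#'
#' @param tallies data.frame from [tally_categories()].
#' @param pairs list of length-2 character vectors naming consecutive
#'   comparisons (first, second); default: consecutive pairs in order of
#'   appearance in `tallies`.
#' @param tau selection threshold in (0, 1\]; the study uses 0.9.
#' @param rule `"or"` (default) or `"and"` combination of the two criteria.
#' @return data.frame with columns `go_code`, `go_name`, `go_domain`,
#'   `first`, `second`, `D1`, `U1`, `D2`, `U2`, `total`, `GRV`, `GNV`,
#'   `selected`.
#' @export
category_dynamics <- function(tallies, pairs = NULL, tau = 0.9,
                              rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
    stop("'tau' must be a single value in (0, 1]")
  comparisons <- unique(tallies$comparison)
  if (is.null(pairs)) {
    if (length(comparisons) < 2) stop("need at least two comparisons")
    pairs <- lapply(seq_len(length(comparisons) - 1L), function(i)
      comparisons[c(i, i + 1L)])
  }
  bad <- setdiff(unlist(pairs), comparisons)
  if (length(bad))
    stop("unknown comparison in 'pairs': ", paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    t1 <- tallies[tallies$comparison == pr[1], ]
    t2 <- tallies[tallies$comparison == pr[2], ]
    idx <- match(t1$go_code, t2$go_code)
    data.frame(go_code = t1$go_code, go_name = t1$go_name,
               go_domain = t1$go_domain, first = pr[1], second = pr[2],
               D1 = t1$D, U1 = t1$U, D2 = t2$D[idx], U2 = t2$U[idx])
  }))
  out$total <- out$D1 + out$U1 + out$D2 + out$U2
  out$GRV <- grv(out$D1, out$U1, out$D2, out$U2)
  out$GNV <- gnv(out$D1, out$U1, out$D2, out$U2)
  crit <- if (rule == "or") abs(out$GRV) > tau | abs(out$GNV) > tau
          else abs(out$GRV) > tau & abs(out$GNV) > tau
  out$selected <- !is.na(crit) & crit
  out <- out[order(-out$total, out$go_code), ]
  rownames(out) <- NULL
  out
}
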