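# Multi-marker complementarity: exclusive-region (Venn) tabulation of
# amplification or identification across 2-3 primer sets on a common taxon
# universe.

#' Per-marker result sets
#'
#' @param name Marker name.
#' @param amplified Vector of taxon keys amplified by the marker.
#' @param identified Vector of taxon keys identified unambiguously (must be
#'   a subset of `amplified`).
#' @return A `marker_result` list.
#' @export
marker_result <- function(name, amplified, identified) {
  amplified <- unique(amplified)
  identified <- unique(identified)
  if (!all(identified %in% amplified)) {
    stop("identified taxa must be a subset of amplified taxa", call. = FALSE)
  }
  structure(list(name = name, amplified = amplified, identified = identified),
            class = "marker_result")
}

#' Convert an evaluation report to a marker result
#'
#' @param report An `eval_report` from [evaluate()].
#' @param name Optional marker name override.
#' @return A [marker_result()].
#' @export
as_marker_result <- function(report, name = NULL) {
  stopifnot(inherits(report, "eval_report"))
  marker_result(name %||% report$marker_name,
                report$amplified_taxa, report$identified_taxa)
}

#' Venn complementarity of 2-3 markers
#'
#' Tabulates the exclusive regions of the marker sets over a shared taxon
#' universe, plus the complement (taxa covered by no marker). In
#' `identification` mode the universe is first restricted to taxa amplified
#' by ALL markers, and membership uses each marker's identified set; in
#' `amplification` mode membership uses the amplified sets. Percentages are
#' rounded half-up to whole percent; raw counts are always exact and sum to
#' the universe size.
#'
#' @param results List of 2-3 [marker_result()] objects.
#' @param universe Vector of taxon keys defining the shared universe.
#' @param mode `"amplification"` or `"identification"`.
#' @return A `venn_report`: tibble with `region` (marker names joined by
#'   `+`, or `"none"`), `count` and `percent`; universe size and mode in
#'   attributes.
#' @export
venn_complementarity <- function(results, universe,
                                 mode = c("amplification", "identification")) {
  mode <- match.arg(mode)
  stopifnot(length(results) %in% c(2L, 3L),
            all(vapply(results, inherits, logical(1), "marker_result")))
  universe <- unique(universe)
  if (mode == "identification") {
    for (r in results) universe <- intersect(universe, r$amplified)
    sets <- lapply(results, function(r) intersect(r$identified, universe))
  } else {
    sets <- lapply(results, function(r) intersect(r$amplified, universe))
  }
  if (length(universe) == 0) {
    stop("empty universe after restriction", call. = FALSE)
  }
  nm <- vapply(results, `[[`, character(1), "name")
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe))
  combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(results))))
  region_name <- apply(combos, 1, function(inc) {
    if (!any(inc)) "none" else paste(nm[inc], collapse = "+")
  })
  count <- apply(combos, 1, function(inc) {
    sum(apply(membership, 1, function(m) all(m == inc)))
  })
  out <- tibble::tibble(
    region = region_name,
    count = as.integer(count),
    percent = round_half_up(100 * count / length(universe))
  )
  structure(out,
            class = c("venn_report", class(tibble::tibble())),
            universe_size = length(universe),
            mode = mode,
            markers = nm)
}

#' Write a Venn report as JSON
#'
#' @param report A `venn_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_venn_report <- function(report, path) {
  payload <- list(
    schema_version = 1L,
    mode = attr(report, "mode"),
    markers = attr(report, "markers"),
    universe_size = attr(report, "universe_size"),
    regions = lapply(seq_len(nrow(report)), function(i) {
      list(region = report$region[i], count = report$count[i],
           percent = report$percent[i])
    })
  )
  .write_atomic(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE)
  }, path)
}

#' Plot a Venn complementarity report
#'
#' Schematic three-circle (or two-circle) diagram annotated with the region
#' percentages; the complement is shown in the corner box.
#'
#' @param object A `venn_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venn_report <- function(object, ...) {
  nm <- attr(object, "markers")
  k <- length(nm)
  centers <- if (k == 3) {
    data.frame(marker = nm, x = c(0, 1, 0.5), y = c(0, 0, 0.87))
  } else {
    data.frame(marker = nm, x = c(0, 1), y = c(0, 0))
  }
  circ <- purrr::map_dfr(seq_len(k), function(i) {
    th <- seq(0, 2 * pi, length.out = 181)
    data.frame(marker = nm[i], x = centers$x[i] + 0.78 * cos(th),
               y = centers$y[i] + 0.78 * sin(th))
  })
  # region label positions: centroid of the member circles, pulled outwards
  # for exclusive regions
  lab <- tibble::as_tibble(object)
  pos <- purrr::map_dfr(seq_len(nrow(lab)), function(i) {
    members <- strsplit(lab$region[i], "+", fixed = TRUE)[[1]]
    if (identical(lab$region[i], "none")) {
      return(data.frame(x = -1.2, y = 1.35))
    }
    sel <- centers[centers$marker %in% members, , drop = FALSE]
    f <- if (nrow(sel) == 1) 1.45 else 1
    ctr <- colMeans(centers[, c("x", "y")])
    data.frame(x = ctr[1] + f * (mean(sel$x) - ctr[1]),
               y = ctr[2] + f * (mean(sel$y) - ctr[2]))
  })
  lab <- dplyr::bind_cols(lab, pos)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$marker,
                                    colour = .data$marker)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sprintf("%d%%", .data$percent)),
                       size = 3.4) +
    ggplot2::annotate("text", x = centers$x, y = centers$y + 0.95,
                      label = nm, fontface = "bold", size = 3.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(
      title = sprintf("Marker complementarity (%s)", attr(object, "mode")),
      subtitle = sprintf("N = %d taxa", attr(object, "universe_size"))
    )
}
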