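# Shareable products: the estimates CSV, the GeoJSON map layer with styling
# metadata, choropleth classification, and plain-language interpretation
# text.  PNG rendering is a front-end concern and deliberately out of scope;
# the GeoJSON + style metadata is the bit-exact deliverable.

#' The six color-blind-friendly map schemes
#'
#' Fixed scheme identifiers with their hex ramps (config data, not logic):
#' three perceptually-uniform sequential ramps (`viridis`, `cividis`,
#' `magma`), two single-hue sequential ramps (`blues`, `oranges`) and one
#' diverging ramp (`purple_green`).
#'
#' @return named list of hex-color character vectors, exactly six schemes.
#' @export
color_schemes <- function() {
  list(
    viridis = c("#440154", "#3B528B", "#21918C", "#5EC962", "#FDE725"),
    cividis = c("#00204D", "#31446B", "#666970", "#A69D75", "#FFEA46"),
    magma = c("#000004", "#51127C", "#B63679", "#FB8861", "#FCFDBF"),
    blues = c("#EFF3FF", "#BDD7E7", "#6BAED6", "#3182BD", "#08519C"),
    oranges = c("#FEEDDE", "#FDBE85", "#FD8D3C", "#E6550D", "#A63603"),
    purple_green = c("#7B3294", "#C2A5CF", "#F7F7F7", "#A6DBA0", "#008837")
  )
}

#' Map styling metadata
#'
#' @param scheme one of the six [color_schemes()] names.
#' @param bins strictly increasing interior break values (from
#'   [classify_bins()]).
#' @param bin_labels optional labels, one per class (`length(bins) + 1`).
#' @param source_note attribution string embedded in exports so audiences can
#'   trace the map back to its producing platform.
#' @return a `map_style` object.
#' @export
map_style <- function(scheme = "viridis", bins = numeric(),
                      bin_labels = NULL,
                      source_note = "Produced with the arearisk small-area mapping pipeline") {
  schemes <- color_schemes()
  if (!scheme %in% names(schemes)) {
    ar_stop("unknown scheme \"", scheme, "\"; available: ",
            paste(names(schemes), collapse = ", "))
  }
  bins <- as.numeric(bins)
  if (length(bins) > 1L && any(diff(bins) <= 0)) {
    ar_stop("bins must be strictly increasing")
  }
  if (is.null(bin_labels)) {
    k <- length(bins) + 1L
    lo <- c("min", formatC(bins, format = "fg"))
    hi <- c(formatC(bins, format = "fg"), "max")
    bin_labels <- paste(lo, hi, sep = " - ")[seq_len(k)]
  }
  structure(list(scheme_name = scheme, colors = schemes[[scheme]],
                 bins = bins, bin_labels = bin_labels,
                 source_note = source_note), class = "map_style")
}

#' Choropleth class breaks
#'
#' Quantile classing puts breaks at the `i/k` empirical quantiles (type-7,
#' the R default); equal-interval classing splits `[min, max]` evenly.  When
#' there are fewer distinct values than classes, quantile mode falls back to
#' equal-interval with a warning; constant input collapses to a single bin.
#'
#' @param values numeric values to classify.
#' @param method `"quantile"` or `"equal_interval"`.
#' @param k number of classes, at least 2.
#' @return numeric vector of `k - 1` interior breaks (possibly shorter after
#'   a degenerate-input fallback).
#' @export
#' @examples
#' classify_bins(1:10, "equal_interval", 5)  # 2.8 4.6 6.4 8.2
classify_bins <- function(values, method = c("quantile", "equal_interval"),
                          k = 5L) {
  method <- match.arg(method)
  stopifnot(k >= 2L)
  values <- values[is.finite(values)]
  if (length(unique(values)) <= 1L) {
    ar_warn("constant values: falling back to a single bin")
    return(numeric())
  }
  if (method == "quantile" && length(unique(values)) < k) {
    ar_warn("fewer distinct values than classes: falling back to equal-interval")
    method <- "equal_interval"
  }
  if (method == "quantile") {
    br <- unname(quantile(values, seq_len(k - 1L) / k, type = 7))
  } else {
    br <- min(values) + seq_len(k - 1L) * diff(range(values)) / k
  }
  br <- unique(br)
  br
}

#' Assign values to style bins
#'
#' A value equal to a break falls in the lower bin; values below the first
#' break are bin 1, above the last break bin `length(bins) + 1`.
#'
#' @param values numeric vector.
#' @param style a [map_style()] (or numeric break vector).
#' @return integer bin index per value.
#' @export
bin_assign <- function(values, style) {
  breaks <- if (inherits(style, "map_style")) style$bins else as.numeric(style)
  findInterval(values, breaks, left.open = TRUE) + 1L
}

#' Export the estimates table as RFC 4180 CSV
#'
#' Header (exactly): `area_id,area_name,site,outcome,sex,race,year,rate,
#' rate_sd,ci_low,ci_high,risk_prob,hotspot,uncertainty,raw_rate,suppressed,
#' events_total,person_years_total`.  Rates carry 1 decimal, probabilities 3;
#' a suppressed raw rate is an empty field with `suppressed=true`.
#'
#' @param rows an [area_estimates()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(rows, path) {
  if (nrow(rows) == 0L) ar_stop("no rows to export")
  query <- attr(rows, "query")
  if (is.null(query)) ar_stop("rows lack their query attribute (subset with filter_estimates)")
  fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  fmt3 <- function(x) sprintf("%.3f", x)
  tab <- data.frame(
    area_id = rows$area_id,
    area_name = rows$area_name,
    site = query$site,
    outcome = query$outcome,
    sex = query$sex,
    race = query$race,
    year = attr(rows, "year_label") %||% "all",
    rate = fmt1(rows$rate),
    rate_sd = fmt1(rows$rate_sd),
    ci_low = fmt1(rows$ci_low),
    ci_high = fmt1(rows$ci_high),
    risk_prob = fmt3(rows$risk_prob),
    hotspot = ifelse(rows$hotspot, "true", "false"),
    uncertainty = rows$uncertainty,
    raw_rate = fmt1(rows$raw_rate),
    suppressed = ifelse(rows$suppressed, "true", "false"),
    events_total = as.character(rows$events_total),
    person_years_total = fmt1(rows$person_years_total),
    stringsAsFactors = FALSE
  )
  esc <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  lines <- c(paste(names(tab), collapse = ","),
             do.call(paste, c(lapply(tab, esc), sep = ",")))
  writeLines(lines, path, sep = "\r\n", useBytes = TRUE)
  invisible(path)
}

#' Export the map layer as GeoJSON with styling metadata
#'
#' Writes an RFC 7946 FeatureCollection: one Feature per estimate row
#' carrying every table field (at the CSV's written precision) plus the
#' assigned style-bin index; the style echo and source note travel as
#' top-level foreign members.  Re-reading the file with [read_geography()]
#' reproduces the adjacency of the input graph.
#'
#' @param rows an [area_estimates()] data frame.
#' @param graph the matching [area_graph()] with polygons.
#' @param style a [map_style()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(rows, graph, style, path) {
  if (is.null(graph$polygons)) ar_stop("graph has no polygons to export")
  idx <- match(rows$area_id, graph$area_ids)
  if (anyNA(idx)) {
    ar_stop("missing polygon for area(s): ",
            paste(rows$area_id[is.na(idx)], collapse = ", "))
  }
  query <- attr(rows, "query")
  if (is.null(query)) ar_stop("rows lack their query attribute (subset with filter_estimates)")
  bins <- bin_assign(rows$rate, style)
  # same written precision as the CSV export (sprintf semantics, not round())
  num1 <- function(x) as.numeric(sprintf("%.1f", x))
  num3 <- function(x) as.numeric(sprintf("%.3f", x))
  feats <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    parts <- graph$polygons[[idx[r]]]
    coords <- lapply(parts, function(part) lapply(part, function(ring) {
      ring <- close_ring(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    }))
    geometry <- if (length(parts) == 1L) {
      list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    feats[[r]] <- list(
      type = "Feature",
      properties = list(
        area_id = rows$area_id[r],
        area_name = rows$area_name[r],
        site = query$site, outcome = query$outcome,
        sex = query$sex, race = query$race,
        year = attr(rows, "year_label") %||% "all",
        rate = num1(rows$rate[r]),
        rate_sd = num1(rows$rate_sd[r]),
        ci_low = num1(rows$ci_low[r]),
        ci_high = num1(rows$ci_high[r]),
        risk_prob = num3(rows$risk_prob[r]),
        hotspot = rows$hotspot[r],
        uncertainty = rows$uncertainty[r],
        raw_rate = if (rows$suppressed[r]) NULL else num1(rows$raw_rate[r]),
        suppressed = rows$suppressed[r],
        events_total = rows$events_total[r],
        person_years_total = num1(rows$person_years_total[r]),
        bin = bins[r]
      ),
      geometry = geometry
    )
  }
  doc <- list(
    type = "FeatureCollection",
    features = feats,
    style = list(scheme_name = style$scheme_name, colors = style$colors,
                 bins = style$bins, bin_labels = style$bin_labels),
    source_note = style$source_note
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @keywords internal
close_ring <- function(ring) {
  k <- nrow(ring)
  if (k > 1L && all(ring[1L, ] == ring[k, ])) ring else rbind(ring, ring[1L, ])
}

#' Plain-language interpretation of one estimate row
#'
#' A deterministic templated sentence naming the area, measure, site,
#' outcome, stratum and value; when the exceedance probability reaches 0.95
#' the text adds that this represents a high probability of cancer burden
#' greater than the overall state.
#'
#' @param row a single-row subset of an [area_estimates()] data frame (its
#'   `query` attribute supplies site/stratum labels; a `query` argument
#'   overrides it).
#' @param query optional normalized query from [validate_query()].
#' @return character scalar.
#' @export
interpretation_text <- function(row, query = NULL) {
  if (is.null(query)) query <- attr(row, "query")
  outcome_phrase <- c(incidence = "incidence",
                      late_stage = "late-stage incidence",
                      mortality = "mortality")[[query$outcome]]
  stratum <- paste0(
    if (identical(query$sex, "all")) "both sexes" else paste0(query$sex, " residents"),
    ", ",
    if (identical(query$race, "all")) "all race groups" else paste0(query$race, " race group"))
  pct <- round(100 * row$risk_prob)
  txt <- sprintf(
    paste0("In %s (area %s), the estimated age-adjusted %s %s rate for %s is ",
           "%.1f per 100,000 person-years (95%% interval %.1f-%.1f). ",
           "The probability that this area's rate exceeds the state average is %d%%."),
    row$area_name, row$area_id, query$site_label %||% query$site, outcome_phrase,
    stratum, row$rate, row$ci_low, row$ci_high, pct)
  if (!is.na(row$risk_prob) && row$risk_prob >= 0.95) {
    txt <- paste0(txt, sprintf(
      " A value of %d%% represents a high probability of cancer burden that is greater than the overall state.",
      pct))
  }
  txt
}
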