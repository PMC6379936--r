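# CSV dialects: comma-separated, UTF-8, '.' decimal separator, mandatory
# header, units embedded in the column names so files cannot silently drift.
TC_COLUMNS <- c("variant", "condition", "replicate", "time_min", "product_nM",
                "substrate_total_nM")
MELT_COLUMNS <- c("variant", "replicate", "temperature_C", "theta222")

.check_header <- function(d, expected, path) {
  if (!identical(names(d), expected)) {
    bm_error(sprintf("'%s': expected header %s, found %s", path,
                     paste(expected, collapse = ","),
                     paste(names(d), collapse = ",")), "parse_error")
  }
}

#' Read excision time courses from CSV
#'
#' Expects exactly the columns `variant, condition, replicate, time_min,
#' product_nM, substrate_total_nM`. Validation errors name the offending
#' file rows (header = row 1).
#'
#' @param path CSV file path.
#' @return List of [time_course()] objects, one per variant x condition,
#'   with replicates folded in.
#' @export
read_time_course_csv <- function(path) {
  if (!file.exists(path)) bm_error(sprintf("no such file: %s", path), "io_error")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_header(d, TC_COLUMNS, path)
  if (!nrow(d)) bm_error(sprintf("'%s': no data rows", path), "parse_error")
  row_no <- seq_len(nrow(d)) + 1L
  bad <- function(cond, what) {
    if (any(cond)) {
      bm_error(sprintf("'%s': %s at row(s) %s", path, what,
                       paste(row_no[cond], collapse = ", ")), "parse_error")
    }
  }
  for (col in c("time_min", "product_nM", "substrate_total_nM")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
    bad(!is.finite(d[[col]]), sprintf("non-numeric %s", col))
  }
  bad(d$time_min < 0, "negative time")
  bad(d$product_nM < 0, "negative product concentration")
  bad(d$substrate_total_nM <= 0, "non-positive substrate total")
  bad(d$product_nM > d$substrate_total_nM + 1e-9,
      "product exceeds the substrate total")
  groups <- split(d, list(d$variant, d$condition), drop = TRUE, sep = "\r")
  out <- lapply(groups, function(g) {
    st <- unique(g$substrate_total_nM)
    if (length(st) != 1L) {
      bm_error(sprintf("'%s': inconsistent substrate total within %s / %s",
                       path, g$variant[1], g$condition[1]), "parse_error")
    }
    time_course(g$variant[1], g$condition[1], g$time_min, g$product_nM,
                replicate = g$replicate, substrate_total = st)
  })
  unname(out)
}

#' Write time courses to CSV
#' @param tcs A [time_course()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_time_course_csv <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  d <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(variant = tc$variant, condition = tc$condition,
               replicate = tc$data$replicate, time_min = tc$data$time,
               product_nM = tc$data$product,
               substrate_total_nM = tc$substrate_total)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read CD melting curves from CSV
#'
#' Expects exactly the columns `variant, replicate, temperature_C, theta222`;
#' returns one curve per variant x replicate, sorted by temperature.
#' Duplicate temperatures within a replicate are rejected.
#'
#' @param path CSV file path.
#' @return List of [melt_curve()] objects.
#' @export
read_melt_csv <- function(path) {
  if (!file.exists(path)) bm_error(sprintf("no such file: %s", path), "io_error")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_header(d, MELT_COLUMNS, path)
  if (!nrow(d)) bm_error(sprintf("'%s': no data rows", path), "parse_error")
  row_no <- seq_len(nrow(d)) + 1L
  for (col in c("temperature_C", "theta222")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
    if (any(!is.finite(d[[col]]))) {
      bm_error(sprintf("'%s': non-numeric %s at row(s) %s", path, col,
                       paste(row_no[!is.finite(d[[col]])], collapse = ", ")),
               "parse_error")
    }
  }
  if (any(d$temperature_C < 0 | d$temperature_C > 100)) {
    bad <- d$temperature_C < 0 | d$temperature_C > 100
    bm_error(sprintf("'%s': temperature outside [0, 100] degC at row(s) %s", path,
                     paste(row_no[bad], collapse = ", ")), "parse_error")
  }
  groups <- split(seq_len(nrow(d)), list(d$variant, d$replicate),
                  drop = TRUE, sep = "\r")
  out <- lapply(groups, function(ix) {
    g <- d[ix, ]
    rn <- row_no[ix]
    ord <- order(g$temperature_C)
    g <- g[ord, ]; rn <- rn[ord]
    dup <- duplicated(g$temperature_C)
    if (any(dup)) {
      bm_error(sprintf("'%s': duplicate temperature within %s replicate %s at row(s) %s",
                       path, g$variant[1], g$replicate[1],
                       paste(rn[dup], collapse = ", ")), "parse_error")
    }
    melt_curve(g$variant[1], g$replicate[1], g$temperature_C, g$theta222)
  })
  unname(out)
}

#' Write melting curves to CSV
#' @param curves A [melt_curve()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(variant = cv$variant, replicate = cv$replicate,
               temperature_C = cv$data$temperature, theta222 = cv$data$theta222)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fit_row <- function(f) {
  data.frame(variant = f$variant, condition = f$condition, model = f$model,
             A0_nM = unname(f$params["A0"]), A0_se = unname(f$se["A0"]),
             k1_per_min = unname(f$params["k1"]), k1_se = unname(f$se["k1"]),
             k2_nM_per_min = unname(f$params["k2"]), k2_se = unname(f$se["k2"]),
             rss = f$rss, n_points = f$n_points)
}

.melt_row <- function(m) {
  data.frame(variant = m$variant, Tm_C = m$tm_mean, Tm_sd = m$tm_sd,
             n_replicates = length(m$tm_values))
}

#' Write fitted results as JSON plus a text report
#'
#' Serializes burst fits, melt averages and a thermolability panel to
#' full-precision JSON (`results.json`) and renders a plain-text report
#' (`report.txt`) whose kinetics table mirrors the conventional summary
#' layout — one row per variant with A0 (nM), k1 (min^-1), k2 (nM min^-1) —
#' followed by a Tm table and the retention panel. Sections without results
#' are omitted with a note.
#'
#' @param fits List of `burst_fit` objects (may be empty).
#' @param melts List of `melt_average` objects (may be empty).
#' @param panels A `thermolability_panel` or `NULL`.
#' @param outdir Output directory, created if needed.
#' @return Invisible list with the two file paths.
#' @export
write_results <- function(fits = list(), melts = list(), panels = NULL, outdir) {
  if (!length(fits) && !length(melts) && is.null(panels)) {
    bm_error("nothing to write: no fits, melts or panels", "io_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) bm_error(sprintf("cannot create '%s'", outdir), "io_error")

  kin_tab <- if (length(fits)) do.call(rbind, lapply(fits, .fit_row)) else NULL
  melt_tab <- if (length(melts)) do.call(rbind, lapply(melts, .melt_row)) else NULL

  payload <- list(
    kinetics = kin_tab,
    thermal = if (length(melts)) {
      lapply(melts, function(m) list(variant = m$variant, Tm_mean = m$tm_mean,
                                     Tm_sd = m$tm_sd, Tm_values = m$tm_values))
    },
    thermolability = if (!is.null(panels)) {
      list(retention = panels$table, protection = panels$protection)
    }
  )
  json_path <- file.path(outdir, "results.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")

  rpt <- c("Analysis report", "===============", "")
  if (!is.null(kin_tab)) {
    rpt <- c(rpt, "Glycosylase activity rate constants", "",
             sprintf("%-10s %-12s %14s %16s %18s", "variant", "condition",
                     "A0 (nM)", "k1 (min^-1)", "k2 (nM min^-1)"),
             vapply(seq_len(nrow(kin_tab)), function(i) {
               r <- kin_tab[i, ]
               if (identical(r$model, "linear_only")) {
                 sprintf("%-10s %-12s %14s %16s %10.3g +/- %.2g", r$variant,
                         r$condition, "-", "-", r$k2_nM_per_min, r$k2_se)
               } else {
                 sprintf("%-10s %-12s %6.3g +/- %.2g %8.3g +/- %.2g %10.3g +/- %.2g",
                         r$variant, r$condition, r$A0_nM, r$A0_se,
                         r$k1_per_min, r$k1_se, r$k2_nM_per_min, r$k2_se)
               }
             }, character(1)), "")
  } else rpt <- c(rpt, "Kinetics section omitted: no burst fits supplied.", "")
  if (!is.null(melt_tab)) {
    rpt <- c(rpt, "Thermal denaturation midpoints", "",
             sprintf("%-10s %12s %10s %6s", "variant", "Tm (degC)", "SD", "n"),
             vapply(seq_len(nrow(melt_tab)), function(i) {
               r <- melt_tab[i, ]
               sprintf("%-10s %12.2f %10s %6d", r$variant, r$Tm_C,
                       if (is.na(r$Tm_sd)) "-" else sprintf("%.2f", r$Tm_sd),
                       r$n_replicates)
             }, character(1)), "")
  } else rpt <- c(rpt, "Thermal section omitted: no melt fits supplied.", "")
  if (!is.null(panels)) {
    tb <- panels$table
    rpt <- c(rpt, "Thermolability (retention after 37 degC challenge)", "",
             sprintf("%-10s %-8s %10s %20s %20s", "variant", "DNA",
                     "retention", "95% CI", "metric"),
             vapply(seq_len(nrow(tb)), function(i) {
               r <- tb[i, ]
               if (is.na(r$retention)) {
                 sprintf("%-10s %-8s %10s %20s %20s", r$variant,
                         if (r$dna) "+DNA" else "none", "missing", "-", "-")
               } else {
                 sprintf("%-10s %-8s %10.3f %9.3f, %6.3f  %20s", r$variant,
                         if (r$dna) "+DNA" else "none", r$retention,
                         r$ci_low, r$ci_high, r$metric)
               }
             }, character(1)), "")
    if (!is.null(panels$protection)) {
      pt <- panels$protection
      rpt <- c(rpt, "DNA protection (delta retention, with - without DNA)", "",
               vapply(seq_len(nrow(pt)), function(i) {
                 r <- pt[i, ]
                 sprintf("  %-10s %+7.3f [%6.3f, %6.3f]  %s", r$variant, r$delta,
                         r$ci_low, r$ci_high,
                         if (r$protective) "protective" else "not protective")
               }, character(1)), "")
    }
  } else rpt <- c(rpt, "Thermolability section omitted: no panel supplied.", "")
  report_path <- file.path(outdir, "report.txt")
  writeLines(rpt, report_path)
  invisible(list(json = json_path, report = report_path))
}
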