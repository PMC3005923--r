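report_sections <- tibble::tribble(
  ~id, ~title,
  "full_sample", "1. Full sample view",
  "stacked", "2. All tiles/panels summary view (stacked x-y)",
  "tiles", "3. Individual tile/panel unevenness",
  "cycles", "4. Cycle-based QC plots",
  "target", "5. Target hit plots",
  "subsets", "6. QC for user-defined sequence lists",
  "pairs", "7. Paired-end/mate-pair library QC"
)

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_page <- function(title, body) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>body{font-family:sans-serif;margin:2em;max-width:70em}",
    "img{max-width:45%;border:1px solid #ccc;margin:0.5em}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 8px}",
    ".note{color:#666;font-style:italic}</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)), body, "</body></html>")
}

# write a plot and the TSV it was drawn from; returns an <figure> fragment
save_plot_with_tsv <- function(p, data, dir, stem, caption, width = 5, height = 4) {
  png_rel <- file.path("plots", paste0(stem, ".png"))
  tsv_rel <- file.path("tsv", paste0(stem, ".tsv"))
  suppressMessages(ggplot2::ggsave(file.path(dir, png_rel), p,
                                   width = width, height = height, dpi = 110))
  readr::write_tsv(data, file.path(dir, tsv_rel))
  sprintf("<figure><img src='%s' alt='%s'><figcaption>%s [<a href='%s'>TSV</a>]</figcaption></figure>",
          png_rel, html_escape(caption), html_escape(caption), tsv_rel)
}

placeholder <- function(msg) sprintf("<p class='note'>%s</p>", html_escape(msg))

#' Render the three-layer HTML quality report
#'
#' Writes a static HTML tree: the top layer lists samples; clicking a
#' sample opens its list of QC measure categories; each category page
#' holds the heat maps, line graphs and bar charts for that measure, every
#' image paired with the TSV file its values came from, so each plot is
#' numerically inspectable. No server is required to view the report (see
#' [serve_report()] for a convenience server). Missing result sets render
#' as an explanatory note, never a broken link, and re-rendering unchanged
#' results produces identical files.
#'
#' @param runs A `seqtileqc_run` (see [run_qc()]) or list of them.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(runs, out_dir) {
  if (inherits(runs, "seqtileqc_run")) runs <- list(runs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  items <- vapply(runs, function(r) {
    render_sample(r, file.path(out_dir, r$name))
    sprintf("<li><a href='%s/index.html'>%s</a></li>", r$name, html_escape(r$name))
  }, character(1))
  writeLines(html_page("Sequencing run QC report",
                       c("<ul>", items, "</ul>")),
             file.path(out_dir, "index.html"))
  invisible(out_dir)
}

render_sample <- function(run, dir) {
  dir.create(file.path(dir, "plots"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tsv"), recursive = TRUE, showWarnings = FALSE)
  sections <- list(
    full_sample = render_full_sample(run, dir),
    stacked = render_stacked(run, dir),
    tiles = render_tiles(run, dir),
    cycles = render_cycles(run, dir),
    target = render_target(run, dir),
    subsets = render_subsets(run, dir),
    pairs = render_pairs(run, dir)
  )
  for (i in seq_len(nrow(report_sections))) {
    id <- report_sections$id[i]
    writeLines(html_page(paste0(run$name, " — ", report_sections$title[i]),
                         c(sections[[id]], "<p><a href='index.html'>back</a></p>")),
               file.path(dir, paste0(id, ".html")))
  }
  g <- glance(run$tile_metrics)
  counters <- sprintf(
    "<p class='note'>reads: %d | coordinate-less: %d | unknown tile: %d | out of bounds: %d</p>",
    g$n_reads, g$n_coordless, g$n_unknown_tile, g$n_out_of_bounds)
  links <- sprintf("<li><a href='%s.html'>%s</a></li>",
                   report_sections$id, report_sections$title)
  writeLines(html_page(paste0("Sample: ", run$name),
                       c(counters, "<ul>", links, "</ul>")),
             file.path(dir, "index.html"))
  invisible(dir)
}

render_full_sample <- function(run, dir) {
  frags <- character()
  for (nm in names(run$sample_grids)) {
    g <- run$sample_grids[[nm]]
    frags <- c(frags, save_plot_with_tsv(
      autoplot(g), tidy(g), dir, paste0("sample_", nm),
      paste0("Per-tile ", attr(g, "metric"))))
  }
  frags
}

render_stacked <- function(run, dir) {
  frags <- character()
  for (nm in names(run$stacked)) {
    g <- run$stacked[[nm]]
    frags <- c(frags, save_plot_with_tsv(
      plot_xy_grid(g, paste0("Stacked ", nm)), g, dir,
      paste0("stacked_", nm), paste0("All tiles stacked: ", nm)))
  }
  frags
}

render_tiles <- function(run, dir) {
  u <- run$unevenness
  readr::write_tsv(u, file.path(dir, "tsv", "unevenness_read_count.tsv"))
  rows <- sprintf("<tr><td>%s</td><td>%.3f</td><td>%d</td></tr>",
                  html_escape(u$tile_id), u$score, as.integer(u$total))
  frags <- c("<h2>Tiles ranked by read-count unevenness</h2>",
             "<p>[<a href='tsv/unevenness_read_count.tsv'>TSV</a>]</p>",
             "<table><tr><th>tile</th><th>score</th><th>reads</th></tr>",
             utils::head(rows, 30L), "</table>")
  if (!is.null(run$hit_unevenness)) {
    readr::write_tsv(run$hit_unevenness,
                     file.path(dir, "tsv", "unevenness_hit_count.tsv"))
    frags <- c(frags,
               "<p>Hit-count ranking: [<a href='tsv/unevenness_hit_count.tsv'>TSV</a>]</p>")
  }
  worst <- u$tile_id[!u$flagged][1]
  if (!is.na(worst)) {
    m <- spatial_composition_map(run$tile_metrics, run$tile_metrics$alphabet[1],
                                 tile_id = worst)
    frags <- c(frags, save_plot_with_tsv(
      plot_xy_grid(m, paste0("Most uneven tile: ", worst)), m, dir,
      "worst_tile_composition",
      paste0("Composition map of the most uneven tile (", worst, ")")))
  }
  frags
}

render_cycles <- function(run, dir) {
  frags <- save_plot_with_tsv(
    plot_cycle_composition(run$cycle_composition), run$cycle_composition,
    dir, "cycle_composition_sample", "Per-cycle composition, sample scope")
  frags <- c(frags, save_plot_with_tsv(
    plot_cycle_composition(run$cycle_by_column, run$tile_metrics$alphabet[1]),
    run$cycle_by_column, dir, "cycle_composition_by_column",
    paste0("Per-cycle '", run$tile_metrics$alphabet[1], "' fraction by tile column")))
  if (!is.null(run$mismatch_rates) && nrow(run$mismatch_rates)) {
    frags <- c(frags, save_plot_with_tsv(
      plot_mismatch_rate(run$mismatch_rates), run$mismatch_rates, dir,
      "mismatch_rate", "Mismatch rate per cycle from unique hits"))
  } else if (is.null(run$mismatch_rates)) {
    frags <- c(frags, placeholder("No alignments supplied: per-cycle mismatch rates unavailable."))
  }
  frags
}

render_target <- function(run, dir) {
  if (is.null(run$target_histogram)) {
    return(placeholder("No alignments supplied: target hit plots unavailable."))
  }
  save_plot_with_tsv(plot_target_histogram(run$target_histogram),
                     run$target_histogram, dir, "target_hits",
                     "Alignment starts binned along the reference")
}

render_subsets <- function(run, dir) {
  if (!length(run$subsets)) {
    return(placeholder("No user-defined read lists supplied."))
  }
  frags <- character()
  for (nm in names(run$subsets)) {
    s <- run$subsets[[nm]]
    side <- paste0(
      save_plot_with_tsv(autoplot(s$subset), tidy(s$subset), dir,
                         paste0("subset_", nm),
                         paste0("Subset '", nm, "' per-tile reads")),
      save_plot_with_tsv(autoplot(s$full), tidy(s$full), dir,
                         paste0("subset_", nm, "_full"),
                         "Whole-sample per-tile reads"))
    t <- s$test
    frags <- c(frags, sprintf("<h2>%s</h2>", html_escape(nm)), side,
               sprintf("<p>Matched reads: %d (unmatched ids: %d). Uniformity against the whole sample: X&#178; = %.2f, df = %d, p = %.3g <span class='note'>(formal test supplementary to the side-by-side visual comparison)</span></p>",
                       s$n_matched, s$n_unmatched, t$statistic, t$df, t$p_value))
  }
  frags
}

render_pairs <- function(run, dir) {
  if (is.null(run$pair_summary)) {
    return(placeholder("No pair configuration supplied: library QC section omitted."))
  }
  ps <- run$pair_summary
  frags <- save_plot_with_tsv(autoplot(ps), tidy(ps), dir, "pair_categories",
                              "Pair category counts")
  if (nrow(ps$distances)) {
    frags <- c(frags, save_plot_with_tsv(
      plot_pair_distances(ps), ps$distances, dir, "pair_distances",
      "Good-pair signed distances split by first-end strand"))
  }
  frags
}

#' Serve a rendered report over HTTP
#'
#' Starts a minimal blocking static-file server on `localhost` so the
#' report can be browsed from another machine; the report itself is plain
#' static HTML, so this is a convenience, not a requirement.
#'
#' @param dir A directory produced by [render_report()].
#' @param port TCP port (default 8080).
#' @param max_requests Stop after this many requests (Inf to run until
#'   interrupted); useful for testing.
#' @return Invisibly, the number of requests served.
#' @export
serve_report <- function(dir, port = 8080L, max_requests = Inf) {
  if (!file.exists(file.path(dir, "index.html"))) {
    stopf("no report at %s: run render_report() (or the 'report' CLI command) first", dir)
  }
  srv <- tryCatch(serverSocket(as.integer(port)),
                  error = function(e) stopf("cannot listen on port %d: %s",
                                            as.integer(port), conditionMessage(e)))
  on.exit(close(srv), add = TRUE)
  inform(sprintf("serving %s on http://localhost:%d/ (Ctrl-C to stop)", dir, port))
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    req <- tryCatch(readLines(con, n = 1L), error = function(e) character())
    path <- serve_resolve_path(dir, req)
    if (is.null(path)) {
      writeLines("HTTP/1.0 404 Not Found\r\nContent-Length: 9\r\n\r\nnot found", con, sep = "")
    } else {
      body <- readBin(path, "raw", file.info(path)$size)
      hdr <- sprintf("HTTP/1.0 200 OK\r\nContent-Type: %s\r\nContent-Length: %d\r\n\r\n",
                     serve_content_type(path), length(body))
      writeBin(c(charToRaw(hdr), body), con)
    }
    close(con)
    served <- served + 1L
  }
  invisible(served)
}

# map a request line onto a file under root, or NULL; rejects path escapes
serve_resolve_path <- function(root, request_line) {
  if (!length(request_line)) return(NULL)
  m <- regmatches(request_line, regexec("^GET\\s+(\\S+)", request_line))[[1]]
  if (length(m) != 2L) return(NULL)
  p <- utils::URLdecode(sub("[?#].*$", "", m[2]))
  if (grepl("\\.\\.", p)) return(NULL)
  p <- sub("^/+", "", p)
  if (p == "" || endsWith(p, "/")) p <- paste0(p, "index.html")
  full <- file.path(root, p)
  if (file.exists(full) && !dir.exists(full)) full else NULL
}

serve_content_type <- function(path) {
  switch(tolower(tools::file_ext(path)),
         html = "text/html; charset=utf-8",
         png = "image/png",
         tsv = "text/tab-separated-values",
         txt = "text/plain",
         css = "text/css",
         "application/octet-stream")
}
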