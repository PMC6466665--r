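# Plain-list view of a report for serialization (gene models are dropped:
# the report is the summary artifact, models are available in R).
.report_to_list <- function(report) {
  st <- report$assembly_stats
  list(per_family = report$per_family,
       summary = list(
         pct_complete = round(report$pct_complete, 8),
         pct_complete_or_partial = round(report$pct_complete_or_partial, 8),
         pct_partial = round(report$pct_partial, 8),
         pct_aberrant = round(report$pct_aberrant, 8),
         pct_missing = round(report$pct_missing, 8),
         hde_detected = report$hde_detected,
         hde_total = report$hde_total,
         pct_hde = if (is.na(report$pct_hde)) NULL else round(report$pct_hde, 8),
         collapse_flags = as.list(report$collapse_flags)),
       assembly_stats = list(
         n_contigs = st$n_contigs, total_length = st$total_length,
         n50_length = st$n50_length, l50_count = st$l50_count,
         max_length = st$max_length, n_fraction = round(st$n_fraction, 8)),
       source_path = if (is.na(report$source_path)) NULL else report$source_path,
       note = report$note)
}

#' Serialize a completeness report
#'
#' TSV output is a per-marker table preceded by `##`-prefixed summary lines;
#' JSON output round-trips through [read_report()] to an equal report and
#' re-serializes byte-identically.
#'
#' @param report A [full_report()] object.
#' @param style `"tsv"` or `"json"`.
#' @param path Optional output file; the text is returned either way.
#' @return The serialized report text (a single string).
#' @export
write_report <- function(report, style = c("tsv", "json"), path = NULL) {
  style <- match.arg(style)
  if (is.null(report$per_family) || nrow(report$per_family) == 0L)
    stop("empty marker set")
  lst <- .report_to_list(report)
  if (style == "json") {
    txt <- as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = 8,
                                         dataframe = "columns", na = "null",
                                         pretty = TRUE))
    txt <- paste0(txt, "\n")
  } else {
    s <- lst$summary
    st <- lst$assembly_stats
    hdr <- c(
      vapply(names(s)[!vapply(s, is.list, logical(1))], function(k) {
        sprintf("## %s\t%s", k, format(s[[k]], scientific = FALSE))
      }, character(1)),
      sprintf("## collapse_flags\t%s",
              if (length(s$collapse_flags)) paste(unlist(s$collapse_flags),
                                                  collapse = ",") else "-"),
      vapply(names(st), function(k) {
        sprintf("## %s\t%s", k, format(st[[k]], scientific = FALSE))
      }, character(1)),
      sprintf("## note\t%s", lst$note))
    df <- report$per_family
    body <- c(paste(names(df), collapse = "\t"),
              vapply(seq_len(nrow(df)), function(i) {
                paste(vapply(df[i, ], function(v) {
                  if (is.na(v)) "NA" else format(v, scientific = FALSE)
                }, character(1)), collapse = "\t")
              }, character(1)))
    txt <- paste0(paste(c(hdr, body), collapse = "\n"), "\n")
  }
  if (!is.null(path)) writeLines(sub("\n$", "", txt), path)
  txt
}

#' Parse a JSON report back into a `completeness_report`
#'
#' @param x JSON text or a path to a JSON report file.
#' @return A `completeness_report` (without the gene-model list).
#' @export
read_report <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    paste(readLines(x), collapse = "\n") else paste(x, collapse = "\n")
  lst <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  pf <- as.data.frame(lst$per_family, stringsAsFactors = FALSE)
  s <- lst$summary
  st <- lst$assembly_stats
  structure(list(per_family = pf,
                 pct_complete = s$pct_complete,
                 pct_complete_or_partial = s$pct_complete_or_partial,
                 pct_partial = s$pct_partial,
                 pct_aberrant = s$pct_aberrant,
                 pct_missing = s$pct_missing,
                 hde_detected = s$hde_detected,
                 hde_total = s$hde_total,
                 pct_hde = if (is.null(s$pct_hde)) NA_real_ else s$pct_hde,
                 collapse_flags = as.character(unlist(s$collapse_flags)),
                 assembly_stats = structure(
                   list(n_contigs = st$n_contigs,
                        total_length = st$total_length,
                        n50_length = st$n50_length,
                        l50_count = st$l50_count,
                        max_length = st$max_length,
                        n_fraction = st$n_fraction),
                   class = "assembly_stats"),
                 source_path = if (is.null(lst$source_path)) NA_character_
                               else lst$source_path,
                 models = NULL,
                 note = lst$note),
            class = "completeness_report")
}
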