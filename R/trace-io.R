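#' Read and write displacement traces
#'
#' Traces are stored as delimited text: a block of `# key: value` header
#' lines carrying the acquisition metadata (beam, feed rate, contact and
#' retraction samples) followed by a CSV body with columns `time_s` and
#' `d_c_mm`. [write_trace()] round-trips everything [read_trace()] parses.
#'
#' @param path File path.
#' @return A trace tibble (`time_s`, `d_c_mm`) with metadata attached as
#'   attributes (`beam`, `insertion_rate_um_s`, `start_index`,
#'   `retraction_index`, `seed` when present).
#' @export
read_trace <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- type.convert(trimws(m[3]), as.is = TRUE)
      meta[[trimws(m[2])]] <- val
    }
  }
  body <- readr::read_csv(I(paste(lines[-hdr], collapse = "\n")),
                          show_col_types = FALSE)
  if (!all(c("time_s", "d_c_mm") %in% names(body))) {
    abort(sprintf("Trace file `%s` must have columns time_s, d_c_mm.", path))
  }
  out <- as_tibble(body)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

#' @rdname read_trace
#' @param trace A trace tibble with metadata attributes.
#' @export
write_trace <- function(trace, path) {
  keep <- c("beam", "insertion_rate_um_s", "start_index", "retraction_index",
            "seed", "sample_period")
  meta <- purrr::compact(purrr::map(rlang::set_names(keep), ~ attr(trace, .x)))
  hdr <- purrr::imap_chr(meta, ~ sprintf("# %s: %s", .y, format(.x, digits = 15)))
  body <- readr::format_csv(tibble(time_s = trace$time_s, d_c_mm = trace$d_c_mm))
  readr::write_lines(c(hdr, sub("\n$", "", body)), path)
  invisible(path)
}
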