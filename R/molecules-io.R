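# BED-like text format for labeled single-molecule sets.
#
#   #repkin-molecules v1
#   #x0 0
#   #L 1000
#   #delta_x 0.1
#   #pbc TRUE
#   #t_window 17760        (optional; synthetic data only)
#   molecule_id<TAB>start_kb<TAB>end_kb<TAB>label[<TAB>t_switch]
#
# One row per run of constant label; label is R (red, first pulse) or G
# (green, second pulse); coordinates are half-open [start, end) in kb
# relative to the genome, and must tile [x0, x0 + L) without overlap.
# The t_switch column is present for simulated molecules and absent for
# real data.

#' Write a molecule set to a BED-like text file
#'
#' @param ms an `"rk_molecules"` set.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_molecules()]
#' @export
write_molecules <- function(ms, path) {
  stopifnot(inherits(ms, "rk_molecules"))
  dx <- ms$x[2] - ms$x[1]
  hdr <- c("#repkin-molecules v1",
           paste("#x0", format(ms$x0)),
           paste("#L", format(ms$L)),
           paste("#delta_x", format(dx)),
           paste("#pbc", isTRUE(ms$pbc)))
  if (!is.null(ms$t_window))
    hdr <- c(hdr, paste("#t_window", format(ms$t_window)))
  has_ts <- !is.null(ms$t_switch) && !anyNA(ms$t_switch)
  rows <- character(0)
  for (i in seq_len(nrow(ms$labels))) {
    l <- ms$labels[i, ]
    brk <- c(0L, which(diff(l) != 0L), length(l))
    for (j in seq_len(length(brk) - 1L)) {
      a <- brk[j] + 1L
      b <- brk[j + 1L]
      row <- paste(i,
                   format(ms$x[a] - dx / 2),
                   format(ms$x[b] + dx / 2),
                   if (l[a] == 1L) "R" else "G",
                   sep = "\t")
      if (has_ts) row <- paste(row, format(ms$t_switch[i]), sep = "\t")
      rows <- c(rows, row)
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a molecule set from a BED-like text file
#'
#' Parses the format written by [write_molecules()]. Files without the
#' `t_switch` column (as for real experimental data) load with `t_switch`
#' set to `NA`. Rows whose intervals overlap within a molecule, fall outside
#' the declared extent, or carry labels other than R/G raise an error naming
#' the line; gaps in coverage raise an error (or a warning when
#' `on_gap = "warn"`).
#'
#' @param path input file.
#' @param on_gap `"error"` or `"warn"` for incomplete molecule coverage.
#' @return An `"rk_molecules"` set.
#' @export
read_molecules <- function(path, on_gap = c("error", "warn")) {
  on_gap <- match.arg(on_gap)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- function(key, default = NULL) {
    m <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (!length(m)) return(default)
    sub(paste0("^#", key, " +"), "", m[1])
  }
  x0 <- as.numeric(meta("x0", "0"))
  L <- as.numeric(meta("L"))
  dx <- as.numeric(meta("delta_x"))
  pbc <- identical(meta("pbc", "FALSE"), "TRUE")
  t_window <- as.numeric(meta("t_window", NA))
  if (is.na(L) || is.na(dx))
    stop("molecule file lacks #L / #delta_x header metadata")

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed row at line ", which(nf < 4)[1] + length(hdr))
  ids <- vapply(fields, `[[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3))
  lab <- vapply(fields, `[[`, character(1), 4)
  ts <- ifelse(nf >= 5, as.numeric(vapply(fields, function(f)
    if (length(f) >= 5) f[[5]] else NA_character_, character(1))), NA_real_)
  if (!all(lab %in% c("R", "G")))
    stop("invalid label (expected R or G) at line ",
         which(!lab %in% c("R", "G"))[1] + length(hdr))
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start))
    stop("invalid interval coordinates at line ",
         which(is.na(start) | is.na(end) | end <= start)[1] + length(hdr))
  if (any(start < x0 - 1e-9) || any(end > x0 + L + 1e-9))
    stop("interval outside declared molecule extent at line ",
         which(start < x0 - 1e-9 | end > x0 + L + 1e-9)[1] + length(hdr))

  n_sites <- round(L / dx)
  x <- x0 + (seq_len(n_sites) - 0.5) * dx
  uid <- unique(ids)
  labels <- matrix(NA_integer_, length(uid), n_sites)
  t_switch <- rep(NA_real_, length(uid))
  for (k in seq_along(uid)) {
    sel <- ids == uid[k]
    s <- start[sel]; e <- end[sel]; lv <- lab[sel]
    o <- order(s)
    s <- s[o]; e <- e[o]; lv <- lv[o]
    if (any(s[-1] < e[-length(e)] - 1e-9))
      stop("overlapping intervals in molecule ", uid[k])
    cover <- sum(e - s)
    if (cover < L - dx / 2) {
      msg <- paste0("molecule ", uid[k], " does not cover its full extent (",
                    format(cover), " of ", format(L), " kb)")
      if (on_gap == "error") stop(msg) else warning(msg)
    }
    for (j in seq_along(s)) {
      idx <- x >= s[j] & x < e[j]
      labels[k, idx] <- if (lv[j] == "R") 1L else 0L
    }
    tsk <- unique(ts[sel][!is.na(ts[sel])])
    if (length(tsk) == 1L) t_switch[k] <- tsk
  }
  fm <- lapply(seq_along(uid), function(k) {
    l <- labels[k, ]
    l[is.na(l)] <- 0L
    fork_marks_from_labels(x, l, pbc = pbc)
  })
  out <- list(labels = labels, x = x, t_switch = t_switch,
              fork_marks = fm, n_attempted = NA_integer_,
              n_full_red = NA_integer_, n_full_green = NA_integer_,
              t_window = t_window, pbc = pbc, L = L, x0 = x0)
  class(out) <- "rk_molecules"
  out
}
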