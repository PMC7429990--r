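#' Acquisition protocols
#'
#' An acquisition protocol is a tibble with one row per acquired volume and
#' columns `volume`, `b` (ms/um^2), `b_delta`, `ax`, `ay`, `az` (encoding
#' symmetry axis), `te` (ms), `shell` (integer id, 0 for b = 0) and `is_b0`.
#' External protocol tables use s/mm^2; conversion happens at the I/O
#' boundary only.
#'
#' @param b,b_delta,axis,te Per-volume encoding parameters; `b` in ms/um^2,
#'   `axis` an n x 3 matrix (defaults to +z).
#' @return A tibble of class `ste_protocol`.
#' @seealso [paper_protocol()], [read_protocol()], [protocol_shells()]
#' @export
ste_protocol <- function(b, b_delta = rep(0, length(b)), axis = NULL,
                         te = rep(88, length(b))) {
  n <- length(b)
  stopifnot(length(b_delta) == n, length(te) == n)
  if (is.null(axis)) axis <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  axis <- as.matrix(axis)
  stopifnot(nrow(axis) == n, ncol(axis) == 3L)
  if (any(b < 0)) abort("b-values must be non-negative.")
  shell_b <- sort(unique(b[b > 0]))
  p <- tibble(
    volume = seq_len(n),
    b = as.numeric(b),
    b_delta = as.numeric(b_delta),
    ax = axis[, 1L], ay = axis[, 2L], az = axis[, 3L],
    te = as.numeric(te),
    shell = ifelse(b > 0, match(b, shell_b), 0L),
    is_b0 = b == 0
  )
  class(p) <- c("ste_protocol", class(p))
  p
}

#' Diffusion shells of a protocol
#'
#' Unique (b, TE) combinations with repetition counts; b = 0 volumes are
#' listed separately with `shell = 0`.
#'
#' @param protocol An [ste_protocol()].
#' @return A tibble with columns `shell`, `b`, `te`, `n`.
#' @export
protocol_shells <- function(protocol) {
  protocol |>
    dplyr::count(.data$shell, .data$b, .data$te, name = "n") |>
    dplyr::arrange(.data$b, .data$te)
}

# b-values (ms/um^2) and per-TE repetitions of the in-vivo STE protocol
STE_SHELLS_B <- c(0.25, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5, 15)
STE_SHELLS_REPS <- c(6, 9, 12, 15, 18, 21, 24, 27, 30, 33, 36)

#' The in-vivo STE acquisition protocol
#'
#' Eleven shells b = 250 ... 15000 s/mm^2 with repetitions 6 ... 36 (231
#' diffusion volumes per TE), shells interleaved over volumes to spread any
#' drift evenly, and a b = 0 volume inserted every 15th image for motion
#' monitoring.
#'
#' @param TEs Echo times in ms (default single TE of 88 ms; the multi-TE
#'   variant uses 88, 115, 140, 165 ms).
#' @param b0_every Insert a b = 0 volume at every `b0_every`-th position.
#' @return An [ste_protocol()] with `231 * length(TEs)` diffusion volumes
#'   plus interleaved b0 volumes.
#' @examples
#' p <- paper_protocol()
#' protocol_shells(p)
#' @export
paper_protocol <- function(TEs = 88, b0_every = 15L) {
  stopifnot(length(TEs) >= 1L, all(TEs > 0))
  # greedy apportionment: at each slot place the shell lagging most behind
  # its target pacing, never repeating the previous shell where avoidable
  n_dwi <- sum(STE_SHELLS_REPS)
  placed <- integer(length(STE_SHELLS_B))
  order_idx <- integer(n_dwi)
  last <- 0L
  for (t in seq_len(n_dwi)) {
    deficit <- STE_SHELLS_REPS * t / n_dwi - placed
    deficit[placed >= STE_SHELLS_REPS] <- -Inf
    cand <- deficit
    if (last > 0L && sum(is.finite(deficit)) > 1L) cand[last] <- -Inf
    last <- which.max(cand)
    placed[last] <- placed[last] + 1L
    order_idx[t] <- last
  }
  dwi_b <- STE_SHELLS_B[order_idx]
  one_te <- function(te) {
    out_b <- numeric(0)
    k <- 0L
    for (bb in dwi_b) {
      if (k %% b0_every == 0L) {
        out_b <- c(out_b, 0)
        k <- k + 1L
      }
      out_b <- c(out_b, bb)
      k <- k + 1L
    }
    out_b
  }
  b_all <- unlist(lapply(TEs, one_te))
  te_all <- rep(TEs, times = vapply(TEs, function(te) length(one_te(te)), 1L))
  ste_protocol(b = b_all, te = te_all)
}

#' Read / write a protocol table
#'
#' Plain-text whitespace-delimited table, one row per volume, columns
#' `b[s/mm2] b_delta ax ay az TE[ms]` (a leading `#` header line is
#' ignored). b-values are converted to ms/um^2 on reading; writing converts
#' back, so a round trip preserves the table bit-exactly.
#'
#' @param path File path.
#' @param protocol An [ste_protocol()].
#' @return `read_protocol()` returns an [ste_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) abort(sprintf("Protocol file '%s' is empty.", path))
  rows <- lapply(keep, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(v) != 6L || anyNA(v)) {
      abort(sprintf("Malformed protocol row at line %d of '%s'.", i, path))
    }
    v
  })
  m <- do.call(rbind, rows)
  ste_protocol(
    b = b_si_to_internal(m[, 1L]), b_delta = m[, 2L],
    axis = m[, 3:5], te = m[, 6L]
  )
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "ste_protocol"))
  lines <- c(
    "# b[s/mm2] b_delta ax ay az TE[ms]",
    vapply(seq_len(nrow(protocol)), function(i) {
      paste(sprintf("%.17g", c(
        b_internal_to_si(protocol$b[i]), protocol$b_delta[i],
        protocol$ax[i], protocol$ay[i], protocol$az[i], protocol$te[i]
      )), collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
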