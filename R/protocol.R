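#' Protocol configuration for one EIT frame
#'
#' Describes how the excitation matrix of a frame is built: how many
#' electrodes surround the domain, how far apart the two drive (current
#' injection) electrodes are, how far apart the two measurement electrodes
#' are, and whether measurement numbering starts just past the drive pair
#' (the device's behaviour) or always at electrode 1.
#'
#' @param n_electrodes Number of electrodes around the boundary (>= 4).
#' @param dist_exc Electrode offset between drive+ and drive- (1 to
#'   `n_electrodes - 1`). The device default of 3 avoids directly adjacent
#'   and oppositional excitation.
#' @param step_meas Electrode offset between measure- and measure+ (1 to
#'   `n_electrodes - 1`).
#' @param rotate_meas If `TRUE` (default, matching the device firmware),
#'   measurement enumeration for each injection starts at the electrode one
#'   past drive-; if `FALSE` it starts at electrode 1.
#' @return An object of class `eit_protocol_config`.
#' @examples
#' eit_protocol_config(16, 3, 1)
#' @export
eit_protocol_config <- function(n_electrodes = 16L, dist_exc = 3L,
                                step_meas = 1L, rotate_meas = TRUE) {
  n <- as.integer(n_electrodes)
  d <- as.integer(dist_exc)
  s <- as.integer(step_meas)
  if (is.na(n) || n < 4L)
    stop("invalid protocol configuration: n_electrodes must be >= 4", call. = FALSE)
  if (is.na(d) || d < 1L || d >= n)
    stop("invalid protocol configuration: dist_exc must be in [1, n_electrodes - 1]",
         call. = FALSE)
  if (is.na(s) || s < 1L || s >= n)
    stop("invalid protocol configuration: step_meas must be in [1, n_electrodes - 1]",
         call. = FALSE)
  structure(list(n_electrodes = n, dist_exc = d, step_meas = s,
                 rotate_meas = isTRUE(rotate_meas)),
            class = "eit_protocol_config")
}

#' @export
print.eit_protocol_config <- function(x, ...) {
  cat("EIT protocol configuration\n")
  cat(sprintf("  electrodes: %d, drive spacing: %d, measurement step: %d, rotated numbering: %s\n",
              x$n_electrodes, x$dist_exc, x$step_meas, x$rotate_meas))
  invisible(x)
}

as_protocol_config <- function(config) {
  if (inherits(config, "eit_protocol_config")) return(config)
  do.call(eit_protocol_config, as.list(config))
}

#' Build the excitation matrix (measurement protocol) for one EIT frame
#'
#' Enumerates every drive/measure electrode quadruple of a frame. Each
#' electrode serves once as drive+ (in ascending order); drive- sits
#' `dist_exc` electrodes above it (wrapping). For each injection, the
#' measure- electrode starts one past drive- and advances around the ring
#' until it returns to drive-, with measure+ `step_meas` electrodes above
#' measure-. Any measurement pair containing either drive electrode is
#' skipped, so every retained quadruple is a true four-electrode
#' measurement.
#'
#' @param config An [eit_protocol_config()] (or a list coercible to one).
#' @return An object of class `eit_protocol`: a data frame with integer
#'   columns `v_plus`, `v_minus`, `m_plus`, `m_minus` (1-based electrode
#'   indices, one row per measurement) and the configuration stored in
#'   `attr(, "config")`.
#' @examples
#' p <- build_protocol(eit_protocol_config(16, 3, 1))
#' nrow(p)   # 192 measurements per frame at the device defaults
#' @seealso [count_measurements()], [write_protocol_csv()]
#' @export
build_protocol <- function(config = eit_protocol_config()) {
  config <- as_protocol_config(config)
  n <- config$n_electrodes
  d <- config$dist_exc
  s <- config$step_meas
  wrap <- function(i) (i - 1L) %% n + 1L
  rows <- vector("list", n)
  for (vp in seq_len(n)) {
    vm <- wrap(vp + d)
    start <- if (config$rotate_meas) wrap(vm + 1L) else 1L
    mm_seq <- wrap(start + 0:(n - 1L))
    mm_seq <- mm_seq[mm_seq != vm]       # sweep ends when measure- reaches drive-
    mp_seq <- wrap(mm_seq + s)
    keep <- mm_seq != vp & mp_seq != vp & mp_seq != vm
    rows[[vp]] <- cbind(vp, vm, mp_seq[keep], mm_seq[keep])
  }
  m <- do.call(rbind, rows)
  out <- data.frame(v_plus = as.integer(m[, 1]), v_minus = as.integer(m[, 2]),
                    m_plus = as.integer(m[, 3]), m_minus = as.integer(m[, 4]))
  attr(out, "config") <- config
  class(out) <- c("eit_protocol", "data.frame")
  out
}

#' Number of measurements in one frame
#'
#' Counts the entries of the excitation matrix for a configuration. For
#' `step_meas = 1` and `1 < dist_exc < n - 1` this equals `n * (n - 4)`
#' (each injection loses the pair overlapping each end of both drive
#' electrodes); the count is always obtained by enumeration so it remains
#' correct for edge configurations where the exclusion slots coincide.
#'
#' @inheritParams build_protocol
#' @return Integer measurement count.
#' @examples
#' count_measurements(eit_protocol_config(16, 3, 1))  # 192
#' @export
count_measurements <- function(config = eit_protocol_config()) {
  nrow(build_protocol(config))
}

#' @export
print.eit_protocol <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("EIT measurement protocol: %d measurements (%d electrodes, dist_exc = %d, step_meas = %d)\n",
              nrow(x), cfg$n_electrodes, cfg$dist_exc, cfg$step_meas))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Export / import a protocol as CSV
#'
#' The CSV carries the four electrode-index columns
#' `v_plus,v_minus,m_plus,m_minus`, one row per measurement.
#'
#' @param protocol An `eit_protocol`.
#' @param path File path.
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "eit_protocol"))
  utils::write.csv(as.data.frame(protocol), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @param n_electrodes Electrode count of the imported protocol (needed to
#'   validate indices; defaults to the largest index present).
#' @export
read_protocol_csv <- function(path, n_electrodes = NULL) {
  df <- utils::read.csv(path)
  need <- c("v_plus", "v_minus", "m_plus", "m_minus")
  if (!all(need %in% names(df)))
    stop("protocol CSV must have columns v_plus,v_minus,m_plus,m_minus", call. = FALSE)
  df <- df[need]
  if (is.null(n_electrodes)) n_electrodes <- max(unlist(df))
  if (any(unlist(df) < 1L | unlist(df) > n_electrodes))
    stop("protocol CSV contains electrode indices outside [1, n_electrodes]", call. = FALSE)
  class(df) <- c("eit_protocol", "data.frame")
  df
}

protocol_n_electrodes <- function(protocol) {
  cfg <- attr(protocol, "config")
  if (!is.null(cfg)) cfg$n_electrodes else max(unlist(protocol[c("v_plus", "v_minus", "m_plus", "m_minus")]))
}
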