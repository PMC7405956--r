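#' @name register
#' @title Frame and strip registration of B-scan stacks
#' @description
#' Multi-frame B-scan averaging proceeds in three steps: every frame is
#' globally aligned to a reference frame by integer-pixel translation at the
#' argmax of the FFT cross-correlation; each aligned frame is then split
#' into lateral strips (blocks of A-scan columns) that are independently
#' re-aligned axially to the reference; finally the frames or strips with
#' the highest normalized cross-correlation (NCC) against the reference,
#' subject to a minimum NCC threshold, are averaged per pixel. NCC is
#' computed on mean-subtracted, unit-variance data over the mutually valid
#' region only; rows/columns that a translation carries out of frame are
#' masked rather than zero-filled.
NULL

# 2-D circular cross-correlation argmax: returns integer (dy, dx) such that
# frame ~ reference shifted by (dy, dx)
xcorr_peak <- function(ref, frame) {
  r <- ref - mean(ref)
  f <- frame - mean(frame)
  X <- Re(fft(Conj(fft(r)) * fft(f), inverse = TRUE))
  idx <- which.max(X)
  nr <- nrow(ref)
  u <- (idx - 1) %% nr
  v <- (idx - 1) %/% nr
  c(dy = if (u <= nr / 2) u else u - nr,
    dx = if (v <= ncol(ref) / 2) v else v - ncol(ref))
}

# 1-D (axial) circular cross-correlation argmax over a column block
xcorr_peak_axial <- function(ref_strip, frame_strip) {
  r <- ref_strip - mean(ref_strip)
  f <- frame_strip - mean(frame_strip)
  s <- rowSums(Conj(stats::mvfft(r)) * stats::mvfft(f))
  X <- Re(fft(s, inverse = TRUE))
  u <- which.max(X) - 1
  nr <- nrow(ref_strip)
  if (u <= nr / 2) u else u - nr
}

# NCC between reference and an aligned frame over the region both cover
# after a (non-circular) translation by (dy, dx)
masked_ncc <- function(ref, aligned, dy = 0, dx = 0) {
  nr <- nrow(ref); nc <- ncol(ref)
  rows <- max(1, 1 + dy):min(nr, nr + dy)
  cols <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rows) < 2 || length(cols) < 2) return(NA_real_)
  a <- as.vector(ref[rows, cols])
  b <- as.vector(aligned[rows, cols])
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Choose a reference frame automatically
#'
#' Among up to 10 evenly sampled frames, picks the one with the maximal
#' mean zero-lag NCC against the other candidates.
#'
#' @param stack a `bscan_stack` or a plain frames array (n x h x w).
#' @return integer frame index.
#' @export
choose_reference <- function(stack) {
  frames <- if (inherits(stack, "bscan_stack")) stack$frames else stack
  n <- dim(frames)[1]
  cand <- unique(round(seq(1, n, length.out = min(10, n))))
  vec <- lapply(cand, function(k) as.vector(frames[k, , ]))
  keep <- vapply(vec, sd, 0) > 0
  cand <- cand[keep]; vec <- vec[keep]
  if (length(cand) == 0L) abort("All candidate frames are constant.")
  if (length(cand) == 1L) return(cand)
  M <- stats::cor(do.call(cbind, vec))
  cand[which.max((rowSums(M) - 1) / (length(cand) - 1))]
}

#' Globally register all frames to a reference
#'
#' Each frame is translated by the integer shift maximising its circular
#' cross-correlation with the reference frame. Constant (degenerate) frames
#' have undefined NCC and are flagged excluded. The reference itself keeps
#' shift (0, 0) and NCC 1.
#'
#' @param stack a `bscan_stack` or frames array (n x h x w), n >= 2.
#' @param ref_index reference frame index, or `NULL` for [choose_reference()].
#' @return list of class `registered_stack` with `frames` (aligned array),
#'   `frame_info` (tibble `frame`, `dy`, `dx`, `ncc`, `excluded`),
#'   `ref_index`, and `meta`.
#' @export
global_register <- function(stack, ref_index = NULL) {
  meta <- if (inherits(stack, "bscan_stack")) stack$meta else list()
  frames <- if (inherits(stack, "bscan_stack")) stack$frames else stack
  n <- dim(frames)[1]
  if (n < 2) abort("Global registration needs at least 2 frames.")
  ref_index <- ref_index %||% choose_reference(frames)
  ref <- frames[ref_index, , ]
  if (sd(ref) == 0) abort("Reference frame is constant; choose another.")
  aligned <- frames
  info <- tibble(frame = seq_len(n), dy = 0L, dx = 0L, ncc = NA_real_,
                 excluded = FALSE)
  for (k in seq_len(n)) {
    if (k == ref_index) {
      info$ncc[k] <- 1
      next
    }
    fr <- frames[k, , ]
    if (sd(fr) == 0) {
      info$excluded[k] <- TRUE
      next
    }
    sh <- xcorr_peak(ref, fr)
    aligned[k, , ] <- circshift2(fr, -sh[["dy"]], -sh[["dx"]])
    info$dy[k] <- as.integer(sh[["dy"]])
    info$dx[k] <- as.integer(sh[["dx"]])
    info$ncc[k] <- masked_ncc(ref, aligned[k, , ])
  }
  structure(list(frames = aligned, frame_info = info, ref_index = ref_index,
                 meta = meta),
            class = "registered_stack")
}

#' Strip-register an aligned stack
#'
#' Partitions each globally aligned frame into contiguous lateral strips
#' (column blocks; a trailing strip narrower than `min_width` is merged into
#' its neighbour) and re-aligns each strip axially to the corresponding
#' reference region, reporting the per-strip shift and post-alignment NCC.
#'
#' @param reg a `registered_stack` from [global_register()].
#' @param strip_width_px strip width in columns (default 64).
#' @param min_width minimum strip width before merging (default 8).
#' @return `reg` with strip-aligned `frames` and an added `strip_info`
#'   tibble (`frame`, `strip`, `col_start`, `col_end`, `dy`, `ncc`).
#' @export
strip_register <- function(reg, strip_width_px = 64, min_width = 8L) {
  stopifnot(inherits(reg, "registered_stack"))
  frames <- reg$frames
  n <- dim(frames)[1]
  ref <- frames[reg$ref_index, , ]
  strips <- strip_bounds(ncol(ref), strip_width_px, min_width)
  rows_out <- vector("list", n)
  for (k in seq_len(n)) {
    fr <- frames[k, , ]
    sdy <- numeric(nrow(strips)); sncc <- numeric(nrow(strips))
    for (s in seq_len(nrow(strips))) {
      cols <- strips$col_start[s]:strips$col_end[s]
      rs <- ref[, cols, drop = FALSE]
      fs <- fr[, cols, drop = FALSE]
      if (k == reg$ref_index || sd(fs) == 0 || sd(rs) == 0) {
        sdy[s] <- 0
        sncc[s] <- if (k == reg$ref_index) 1 else NA_real_
        next
      }
      d <- xcorr_peak_axial(rs, fs)
      al <- circshift2(fs, -d, 0)
      fr[, cols] <- al
      sdy[s] <- d
      sncc[s] <- masked_ncc(rs, al, dy = d)
    }
    frames[k, , ] <- fr
    rows_out[[k]] <- tibble(frame = k, strip = strips$strip,
                            col_start = strips$col_start,
                            col_end = strips$col_end,
                            dy = as.integer(sdy), ncc = sncc)
  }
  reg$frames <- frames
  reg$strip_info <- bind_rows(rows_out)
  reg
}

#' Select high-NCC units and average
#'
#' Ranks registration units (whole frames, or strips when `strip_info` is
#' present and `unit = "strip"`) by NCC in descending order, keeps those
#' meeting the minimum threshold, caps the count at `max_frames` (per strip
#' position in strip mode, so parts of frames can enter the average), and
#' averages per pixel with a coverage count. Ties in NCC are broken by frame
#' index (earlier frame wins), making selection deterministic.
#'
#' @param reg a `registered_stack`.
#' @param threshold minimum NCC (default 0.85).
#' @param max_frames maximum units averaged (per strip position), default 30.
#' @param unit `"frame"` or `"strip"`.
#' @return list of class `averaged_scan`: `image` (matrix), `coverage`
#'   (matrix of per-pixel counts), `report` (tibble of all units with `ncc`,
#'   `included`, `reason`), `n_included`.
#' @export
select_and_average <- function(reg, threshold = 0.85, max_frames = 30,
                               unit = c("frame", "strip")) {
  stopifnot(inherits(reg, "registered_stack"))
  unit <- match.arg(unit)
  frames <- reg$frames
  h <- dim(frames)[2]; w <- dim(frames)[3]
  if (unit == "strip" && is.null(reg$strip_info)) {
    abort("Run strip_register() before strip-wise selection.")
  }
  if (unit == "frame") {
    units <- reg$frame_info
    units$strip <- 1L
    units$col_start <- 1L
    units$col_end <- w
  } else {
    units <- left_join(reg$strip_info,
                       select(reg$frame_info, "frame", "excluded"),
                       by = "frame")
  }
  units$excluded <- units$excluded %||% FALSE
  units <- units |>
    mutate(eligible = !.data$excluded & !is.na(.data$ncc) & .data$ncc >= threshold) |>
    group_by(.data$strip) |>
    arrange(desc(.data$ncc), .data$frame, .by_group = TRUE) |>
    mutate(rank = cumsum(.data$eligible),
           included = .data$eligible & .data$rank <= max_frames,
           reason = case_when(
             .data$included ~ "included",
             .data$eligible ~ "over_max_frames",
             is.na(.data$ncc) | .data$excluded ~ "degenerate",
             TRUE ~ "below_threshold"
           )) |>
    ungroup() |>
    arrange(.data$strip, .data$frame)
  if (!any(units$included)) {
    abort("NO_FRAMES_PASS_NCC: no registration unit meets the NCC threshold.")
  }
  acc <- matrix(0, h, w)
  cov <- matrix(0L, h, w)
  inc <- units[units$included, ]
  for (i in seq_len(nrow(inc))) {
    cols <- inc$col_start[i]:inc$col_end[i]
    acc[, cols] <- acc[, cols] + frames[inc$frame[i], , cols]
    cov[, cols] <- cov[, cols] + 1L
  }
  img <- acc
  img[cov > 0] <- acc[cov > 0] / cov[cov > 0]
  structure(list(image = img, coverage = cov,
                 report = select(units, -"eligible", -"rank"),
                 n_included = sum(units$included), meta = reg$meta),
            class = "averaged_scan")
}

#' Register and average a stack end to end
#'
#' Convenience chain: [choose_reference()] (unless given),
#' [global_register()], [strip_register()], [select_and_average()].
#'
#' @inheritParams global_register
#' @inheritParams select_and_average
#' @param strip_width_px strip width (columns); `NULL` skips strip
#'   registration and selects whole frames.
#' @return an `averaged_scan`, with the `registered_stack` attached as
#'   attribute `"registration"`.
#' @export
register_stack <- function(stack, ref_index = NULL, threshold = 0.85,
                           max_frames = 30, strip_width_px = 64) {
  reg <- global_register(stack, ref_index)
  if (!is.null(strip_width_px)) {
    reg <- strip_register(reg, strip_width_px)
    avg <- select_and_average(reg, threshold, max_frames, unit = "strip")
  } else {
    avg <- select_and_average(reg, threshold, max_frames, unit = "frame")
  }
  attr(avg, "registration") <- reg
  avg
}
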