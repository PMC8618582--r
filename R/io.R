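#' Write / read a contact map as dense TSV
#'
#' The dense dialect stores the full symmetric matrix with a header row
#' naming the 0-based half-open genomic bin starts
#' (`bin_<start>`). The sparse dialect stores upper-triangle triplets
#' `bin_i, bin_j, value` (1-based bin indices); absent cells read back
#' as zero.
#'
#' @param map a `contact_map` or plain symmetric matrix.
#' @param path output file.
#' @param format "dense" or "sparse".
#' @param resolution bin size in bp (for the dense header).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(map, path, format = c("dense", "sparse"),
                                 resolution = 1e5) {
  format <- match.arg(format)
  v <- if (inherits(map, "contact_map")) map$values else map
  if (format == "dense") {
    colnames(v) <- paste0("bin_", format((seq_len(ncol(v)) - 1) *
                                           resolution,
                                         scientific = FALSE, trim = TRUE))
    write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(v) & v != 0, arr.ind = TRUE)
    df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                     value = v[idx])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param n matrix size (required to reconstruct from sparse triplets
#'   when trailing bins are empty; default: largest index present).
#' @param normalize return relative frequencies (s = 1 excluded) via
#'   the standard normalization instead of raw values.
#' @param spec optional [chromosome_spec()] whose masks apply when
#'   normalizing.
#' @export
read_contact_matrix <- function(path, format = c("dense", "sparse"),
                                n = NULL, normalize = FALSE,
                                spec = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    v <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
    dimnames(v) <- NULL
  } else {
    df <- read.table(path, sep = "\t", header = TRUE)
    if (is.null(n)) n <- max(df$bin_i, df$bin_j)
    v <- matrix(0, n, n)
    v[cbind(df$bin_i, df$bin_j)] <- df$value
    v[cbind(df$bin_j, df$bin_i)] <- df$value
  }
  if (any(v < 0)) stop("negative values in contact matrix")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
    stop("asymmetric contact matrix")
  if (normalize) relative_contact_map(v, spec)
  else new_contact_map(v, "counts", spec)
}

#' Write / read a per-bin profile as bedGraph
#'
#' Standard 4-column bedGraph (chrom, start, end, value) with 0-based
#' half-open intervals. On reading, the resolution is inferred from
#' the interval widths; overlapping intervals and mixed widths are
#' rejected, except that a contiguous higher-resolution sub-region is
#' accepted and reported through the `exempt` attribute.
#'
#' @param values numeric vector of per-bin values.
#' @param path file path.
#' @param chrom chromosome label.
#' @param resolution bin width, bp.
#' @param bin_origin genomic start of bin 1, bp.
#' @return `path` invisibly (write); numeric vector with attributes
#'   `chrom`, `resolution`, `starts` (read).
#' @export
write_profile <- function(values, path, chrom = "chr", resolution = 1e5,
                          bin_origin = 0) {
  starts <- bin_origin + (seq_along(values) - 1) * resolution
  df <- data.frame(chrom = chrom, start = format(starts, scientific = FALSE,
                                                 trim = TRUE),
                   end = format(starts + resolution, scientific = FALSE,
                                trim = TRUE),
                   value = values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  o <- order(df$start)
  df <- df[o, ]
  if (any(df$end[-nrow(df)] > df$start[-1]))
    stop("overlapping intervals in profile")
  widths <- as.numeric(df$end - df$start)
  res <- max(widths)
  if (length(unique(widths)) > 2)
    stop("more than two interval widths in profile")
  out <- df$value
  attr(out, "chrom") <- df$chrom[1]
  attr(out, "resolution") <- res
  attr(out, "starts") <- df$start
  if (length(unique(widths)) == 2) {
    fine <- widths == min(widths)
    if (any(diff(which(fine)) != 1))
      stop("mixed widths outside one contiguous high-resolution region")
    attr(out, "exempt") <- which(fine)
    attr(out, "fine_resolution") <- min(widths)
  }
  out
}

#' Write / read a multi-frame XYZ trajectory
#'
#' One record per frame: a bead-count line, a comment line
#' (`frame <k>`), then one `C x y z` line per bead in chain order.
#'
#' @param traj a `trajectory` or list of conformations.
#' @param path file path.
#' @return `path` invisibly (write); list of `conformation` objects
#'   (read).
#' @export
write_xyz <- function(traj, path) {
  frames <- if (inherits(traj, "trajectory"))
    lapply(seq_len(dim(traj)[3]), function(f) trajectory_frame(traj, f))
  else traj
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    m <- unclass_conf(frames[[k]])
    writeLines(as.character(nrow(m)), con)
    writeLines(paste("frame", k), con)
    writeLines(sprintf("C %.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(block, "\\s+"))
    m <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    frames[[length(frames) + 1]] <- new_conformation(m)
    i <- i + 2 + n
  }
  frames
}

#' Write ensemble metadata sidecar
#'
#' Tab-separated record of seed, ensemble size and potential-field
#' checksum next to an exported ensemble.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_metadata <- function(ensemble, path) {
  pv <- ensemble$provenance
  df <- data.frame(field = c("seed", "K", "checksum"),
                   value = c(pv$seed %||% NA, length(ensemble),
                             pv$checksum %||% NA))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
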