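TRAJ_MAGIC <- "dynloop-trajectory"
TRAJ_VERSION <- 1L

frame_checksum <- function(positions, links) {
  v <- c(as.numeric(positions), as.numeric(links))
  as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Write a trajectory to a plain-text file
#'
#' The format is a versioned, self-describing text container: a magic
#' line, a single-line JSON header (chain length, box, model parameters,
#' schedule, provenance), then one block per frame carrying the sweep
#' index, the integer monomer positions and the active cross-link
#' triples, each with a checksum, and a trailing end line with the frame
#' count.  Re-serializing a read trajectory reproduces the file
#' byte-for-byte.
#'
#' @param traj A `dl_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
dl_write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dl_trajectory"))
  header <- jsonlite::toJSON(list(
    n = traj$n, box = traj$box,
    params = unclass(traj$params),
    schedule = unclass(traj$schedule),
    provenance = traj$provenance), auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s %d", TRAJ_MAGIC, TRAJ_VERSION), con)
  writeLines(as.character(header), con)
  for (fr in traj$frames) {
    writeLines(sprintf("frame %s %d %d %d",
                       format(fr$sweep, scientific = FALSE),
                       nrow(fr$positions), nrow(fr$links),
                       frame_checksum(fr$positions, fr$links)), con)
    writeLines(paste(fr$positions[, 1], fr$positions[, 2],
                     fr$positions[, 3]), con)
    if (nrow(fr$links) > 0L)
      writeLines(paste(fr$links[, 1], fr$links[, 2], fr$links[, 3]), con)
  }
  writeLines(sprintf("end %d", length(traj$frames)), con)
  invisible(path)
}

#' Read a trajectory file
#'
#' Performs full integrity checking: magic/version mismatch, truncation
#' (missing frame lines or missing end line) and per-frame checksum
#' failures are reported as distinct errors naming the offending frame.
#'
#' @param path File written by [dl_write_trajectory()].
#' @return A `dl_trajectory` (without the per-sweep observable series,
#'   which are not part of the on-disk format).
#' @export
dl_read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("truncated file: empty")
  magic <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(magic) != 2L || magic[1] != TRAJ_MAGIC)
    stop("not a dynloop trajectory file")
  if (length(lines) < 2L) stop("truncated file: missing header")
  if (as.integer(magic[2]) != TRAJ_VERSION)
    stop(sprintf("version mismatch: file version %s, supported %d",
                 magic[2], TRAJ_VERSION))
  header <- jsonlite::fromJSON(lines[2])
  pos <- 3L
  frames <- list()
  n_declared <- NA_integer_
  repeat {
    if (pos > length(lines)) stop("truncated file: missing end line")
    tok <- strsplit(lines[pos], " ", fixed = TRUE)[[1]]
    if (tok[1] == "end") {
      n_declared <- as.integer(tok[2])
      break
    }
    if (tok[1] != "frame")
      stop(sprintf("corrupt frame header at line %d", pos))
    sweep <- as.numeric(tok[2])
    np <- as.integer(tok[3]); nl <- as.integer(tok[4])
    cks <- as.integer(tok[5])
    need <- np + nl
    if (pos + need > length(lines))
      stop(sprintf("truncated file: frame %d incomplete", length(frames) + 1L))
    pmat <- matrix(as.integer(scan(
      text = lines[(pos + 1L):(pos + np)], quiet = TRUE)), ncol = 3,
      byrow = TRUE)
    lmat <- if (nl > 0L)
      matrix(as.integer(scan(
        text = lines[(pos + np + 1L):(pos + np + nl)], quiet = TRUE)),
        ncol = 3, byrow = TRUE)
    else matrix(integer(0), 0L, 3L)
    if (frame_checksum(pmat, lmat) != cks)
      stop(sprintf("checksum failure in frame %d", length(frames) + 1L))
    frames[[length(frames) + 1L]] <- dl_conformation(
      pmat, lmat, sweep, box = header$box, validate = FALSE)
    pos <- pos + need + 1L
  }
  if (n_declared != length(frames))
    stop(sprintf("truncated file: %d frames declared, %d found",
                 n_declared, length(frames)))
  params <- do.call(dl_params, header$params)
  schedule <- do.call(dl_schedule, header$schedule)
  structure(list(frames = frames, n = as.integer(header$n),
                 box = as.integer(header$box), params = params,
                 schedule = schedule, series = NULL, final = NULL,
                 provenance = header$provenance),
            class = "dl_trajectory")
}

CONFIG_KEYS <- c("n", "cutoff", "p_form", "target_concentration", "lifetime",
                 "max_links", "force", "stage1", "stage2", "sampling",
                 "stride", "seed", "box", "theta", "window_constant", "m",
                 "kT")

#' Load a run configuration from YAML
#'
#' Resolves every documented default and echoes the full resolved
#' parameter set.  The only required key is `n` (chain length); unknown
#' keys are an error, as are out-of-range values.  `p_form` may be given
#' directly, or `target_concentration` may be given instead, in which
#' case the caller is expected to run [dl_calibrate_p()].
#'
#' @param path Path to a YAML file.
#' @return A list with `n`, `params` (`dl_params`), `schedule`
#'   (`dl_schedule`), `box`, `target_concentration` and `analysis`
#'   (list of `theta`, `window_constant`, `m`, `kT`).
#' @export
dl_load_config <- function(path) {
  # keep short keys like "n" literal (YAML 1.1 would read them as booleans)
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(raw$n)) stop("missing required key: n")
  get <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  params <- dl_params(
    cutoff = get("cutoff", 50L),
    p_form = get("p_form", 0),
    lifetime = get("lifetime", 100),
    max_links = get("max_links", 4L),
    force = get("force", 0))
  schedule <- dl_schedule(
    stage1 = get("stage1", 10000),
    stage2 = get("stage2", 10000),
    sampling = get("sampling", 10000),
    stride = get("stride", 500L),
    seed = get("seed", 1L))
  kT <- get("kT", 1)
  if (kT != 1) stop("kT is fixed to 1 (forces are in kT per lattice unit)")
  list(n = as.integer(raw$n),
       params = params,
       schedule = schedule,
       box = get("box", dl_default_box(raw$n)),
       target_concentration = get("target_concentration", NULL),
       analysis = list(theta = get("theta", 0.9),
                       window_constant = get("window_constant", 6),
                       m = get("m", NULL),
                       kT = kT))
}
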