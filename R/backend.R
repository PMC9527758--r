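# File-exchange protocol for external electronic-structure backends and
# standard XYZ geometry I/O. The driver writes the current geometry to
# system.xyz (Angstrom), invokes a user-configured command, and parses the
# energies/gradients (and optional oscillator strengths and state expansion
# vectors) the backend writes to interface.dat.

#' Write an XYZ geometry file
#'
#' @param file output path.
#' @param R `n x 3` geometry in Bohr (converted to Angstrom on output), or a
#'   list of such matrices for a multi-frame file.
#' @param atoms character element labels.
#' @param comment comment line(s).
#' @param append append to an existing file.
#' @export
write_xyz <- function(file, R, atoms, comment = "", append = FALSE) {
  frames <- if (is.list(R)) R else list(R)
  comment <- rep_len(comment, length(frames))
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    Ra <- bohr_to_ang(matrix(frames[[k]], ncol = 3))
    writeLines(as.character(nrow(Ra)), con)
    writeLines(comment[k], con)
    writeLines(sprintf("%-4s %18.10f %18.10f %18.10f",
                       atoms, Ra[, 1], Ra[, 2], Ra[, 3]), con)
  }
  invisible(file)
}

#' Read an XYZ geometry file
#'
#' @param file path to a (possibly multi-frame) XYZ file in Angstrom.
#' @return list with `atoms` (labels of the first frame), `frames` (list of
#'   `n x 3` matrices in Bohr) and `comments`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); comments <- character(0); atoms <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad atom count at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated frame starting at line ", i)
    comments <- c(comments, lines[i + 1])
    rec <- do.call(rbind, lapply(lines[(i + 2):(i + 1 + n)], function(l) {
      strsplit(trimws(l), "\\s+")[[1]]
    }))
    if (is.null(atoms)) atoms <- rec[, 1]
    frames[[length(frames) + 1]] <-
      ang_to_bohr(matrix(as.numeric(rec[, 2:4]), n, 3))
    i <- i + 2 + n
  }
  list(atoms = atoms, frames = frames, comments = comments)
}

#' Write an interface.dat result file
#'
#' Serializes electronic-structure results in the documented fixed layout
#' consumed by [read_interface_dat()] (used by mock backends and by tests).
#'
#' @param file output path.
#' @param energies state energies (Hartree, ascending).
#' @param gradients `n_states x n_atoms x 3` array (Hartree/Bohr).
#' @param f optional oscillator strengths (from the ground state; the
#'   leading ground-state entry is dropped on output).
#' @param U optional square state-expansion matrix (one row per line).
#' @export
write_interface_dat <- function(file, energies, gradients, f = NULL, U = NULL) {
  n_states <- length(energies)
  n_atoms <- dim(gradients)[2]
  out <- c(paste("nstates", n_states), paste("natoms", n_atoms), "energies",
           sprintf("%.16e", energies))
  for (I in seq_len(n_states)) {
    out <- c(out, paste("gradient", I),
             sprintf("%.16e %.16e %.16e", gradients[I, , 1],
                     gradients[I, , 2], gradients[I, , 3]))
  }
  if (!is.null(f))
    out <- c(out, "oscillator_strengths", sprintf("%.16e", f[-1]))
  if (!is.null(U)) {
    out <- c(out, "expansion",
             apply(U, 1, function(r) paste(sprintf("%.16e", r), collapse = " ")))
  }
  writeLines(c(out, "end"), file)
  invisible(file)
}

#' Parse an interface.dat result file
#'
#' Layout: `nstates <N>` / `natoms <M>` headers; an `energies` block with
#' one Hartree value per line; one `gradient <I>` block per state with `M`
#' lines of three Hartree/Bohr components; optional `oscillator_strengths`
#' (N-1 lines) and `expansion` (N rows of N values) blocks; a final `end`.
#' Parse failures report the offending line.
#'
#' @param file path to the file.
#' @return list with `energies`, `gradients` (`N x M x 3`), `f`, `U`.
#' @export
read_interface_dat <- function(file) {
  if (!file.exists(file)) stop("interface file not found: ", file)
  lines <- trimws(readLines(file))
  pos <- 1; cur <- 1
  fail <- function(msg) stop("interface.dat parse error at line ", cur, ": ", msg)
  take <- function() {
    cur <<- pos
    if (pos > length(lines)) fail("unexpected end of file")
    l <- lines[pos]; pos <<- pos + 1; l
  }
  expect_kv <- function(key) {
    parts <- strsplit(take(), "\\s+")[[1]]
    if (length(parts) != 2 || parts[1] != key) fail(paste("expected", key))
    v <- suppressWarnings(as.integer(parts[2]))
    if (is.na(v)) fail(paste("bad", key, "value"))
    v
  }
  num_line <- function(k, what) {
    v <- suppressWarnings(as.numeric(strsplit(take(), "\\s+")[[1]]))
    if (length(v) != k || any(is.na(v))) fail(paste("bad", what))
    v
  }
  n_states <- expect_kv("nstates")
  n_atoms <- expect_kv("natoms")
  if (take() != "energies") { pos <- pos - 1; fail("expected energies block") }
  energies <- vapply(seq_len(n_states), function(i)
    num_line(1, paste("energy of state", i)), numeric(1))
  gradients <- array(NA_real_, c(n_states, n_atoms, 3))
  for (I in seq_len(n_states)) {
    hdr <- strsplit(take(), "\\s+")[[1]]
    if (length(hdr) != 2 || hdr[1] != "gradient" || as.integer(hdr[2]) != I) {
      pos <- pos - 1; fail(paste("expected gradient block for state", I))
    }
    for (a in seq_len(n_atoms))
      gradients[I, a, ] <- num_line(3, paste("gradient of state", I, "atom", a))
  }
  f <- NULL; U <- NULL
  repeat {
    l <- take()
    if (l == "end") break
    if (l == "oscillator_strengths") {
      f <- c(0, vapply(seq_len(n_states - 1), function(i)
        num_line(1, paste("oscillator strength", i + 1)), numeric(1)))
    } else if (l == "expansion") {
      U <- do.call(rbind, lapply(seq_len(n_states), function(i)
        num_line(n_states, paste("expansion row", i))))
    } else {
      pos <- pos - 1; fail(paste("unknown block:", l))
    }
  }
  list(energies = energies, gradients = gradients, f = f, U = U)
}

#' Evaluate a geometry through an external backend
#'
#' Writes `system.xyz` into `workdir`, runs the configured command there,
#' and parses the `interface.dat` it must produce. The command receives no
#' arguments beyond those baked into `command`/`args`; the exchange is
#' purely file-based.
#'
#' @param command executable (or script) to invoke.
#' @param args character vector of arguments.
#' @param workdir working directory for the exchange files.
#' @param R geometry (`n x 3`, Bohr).
#' @param atoms element labels.
#' @param n_states expected number of states.
#' @return list with class `electronic_result` holding `energies`,
#'   `gradients`, `f` (zeros when the backend omits them) and `U` (identity
#'   when omitted).
#' @export
external_backend <- function(command, args = character(), workdir, R, atoms,
                             n_states) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(file.path(workdir, "system.xyz"), R, atoms)
  datfile <- file.path(workdir, "interface.dat")
  if (file.exists(datfile)) file.remove(datfile)
  out <- suppressWarnings(
    system2(command, args, stdout = TRUE, stderr = TRUE))
  rc <- attr(out, "status")
  if (!is.null(rc) && rc != 0)
    stop("backend exited with status ", rc, ":\n",
         paste(out, collapse = "\n"))
  parsed <- read_interface_dat(datfile)
  if (length(parsed$energies) != n_states)
    stop("backend returned ", length(parsed$energies), " states, expected ",
         n_states)
  structure(list(energies = parsed$energies, gradients = parsed$gradients,
                 f = if (is.null(parsed$f)) numeric(n_states) else parsed$f,
                 U = if (is.null(parsed$U)) diag(n_states) else parsed$U,
                 state_charges = NULL, trans_charges = NULL,
                 lr_shifts = numeric(n_states)),
            class = "electronic_result")
}

#' Write trajectory output files
#'
#' Per-trajectory artifacts: a multi-frame XYZ file, a CSV step log, and a
#' JSON end-of-run record (status, internal-conversion time, seed).
#'
#' @param traj a `trajectory`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `traj<id>`.
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, dir, name = NULL) {
  if (is.null(name)) name <- paste0("traj", traj$trajectory_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- rep("X", nrow(traj$frames[[1]]))
  atoms[traj$qm_mask] <- traj$atoms
  xyz <- file.path(dir, paste0(name, ".xyz"))
  write_xyz(xyz, traj$frames, atoms,
            comment = sprintf("t= %.3f fs", c(0, traj$log$t_fs)))
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(traj$log, csv, row.names = FALSE)
  js <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(status = traj$status, t_end_fs = traj$t_end_fs,
                            t_ic_fs = traj$t_ic_fs, valid = traj$valid,
                            seed = traj$seed, id = traj$trajectory_id),
                       js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(xyz = xyz, csv = csv, json = js))
}
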