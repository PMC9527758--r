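# JSON configuration readers for MM site sets and diabatic models. Lengths
# in the config files are Angstrom and polarizabilities Angstrom^3 (converted
# on read); energies and charges are atomic units.

#' Read an MM site definition (JSON)
#'
#' Expected fields: `sites`, an array of objects with `position` (Angstrom),
#' optional `charge`, `dipole`, `quadrupole` (3x3, traceless), `alpha`
#' (Angstrom^3); optional top-level `exclude_p`, `exclude_d` (arrays of
#' 1-based index pairs), `scale_p`, `scale_d`, `damping`.
#'
#' @param file path to a JSON file.
#' @return a `multipole_set`.
#' @export
read_multipole_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  sites <- cfg$sites
  if (is.null(sites)) stop("config has no 'sites' field")
  if (is.data.frame(sites)) {
    pos <- do.call(rbind, sites$position)
    n <- nrow(pos)
    charges <- if (!is.null(sites$charge)) replace_na(sites$charge) else numeric(n)
    alphas <- if (!is.null(sites$alpha)) replace_na(sites$alpha) else numeric(n)
    dipoles <- if (!is.null(sites$dipole))
      do.call(rbind, lapply(sites$dipole, function(d) if (is.null(d)) c(0, 0, 0) else d))
      else NULL
    quads <- NULL
    if (!is.null(sites$quadrupole)) {
      quads <- array(0, c(n, 3, 3))
      for (i in seq_len(n)) {
        q <- sites$quadrupole[[i]]
        if (!is.null(q)) quads[i, , ] <- matrix(unlist(q), 3, 3)
      }
    }
  } else stop("'sites' must be an array of site objects")
  multipole_set(ang_to_bohr(pos), charges = charges, dipoles = dipoles,
                quadrupoles = quads, alphas = ang3_to_bohr3(alphas),
                exclude_p = to_pairs(cfg$exclude_p),
                exclude_d = to_pairs(cfg$exclude_d),
                scale_p = cfg$scale_p %||% 0, scale_d = cfg$scale_d %||% 0,
                damping = cfg$damping)
}

replace_na <- function(x) { x[is.na(x)] <- 0; x }
to_pairs <- function(x) if (is.null(x) || length(x) == 0) NULL else
  matrix(as.integer(unlist(x)), ncol = 2, byrow = !is.matrix(x))
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a diabatic model definition (JSON)
#'
#' Schema: `n_states`, `n_atoms`, `atoms` (labels), `terms` (array per
#' state; each term an object with `type` = harm/morse/rep/const and the
#' corresponding parameters, distances in Bohr and energies in Hartree),
#' `couplings`, `state_charges`, `trans_charges` (state x atom matrices),
#' `trans_dipoles` (list of `{i, j, mu}`), `ct_labels`.
#'
#' @param file path to a JSON file.
#' @return a `diabatic_model`.
#' @export
read_model_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = FALSE)
  ns <- cfg$n_states; na <- cfg$n_atoms
  terms <- lapply(cfg$terms, function(state_terms)
    lapply(state_terms, function(tm) lapply(tm, unlist)))
  couplings <- lapply(cfg$couplings %||% list(), function(cp) {
    cp$i <- as.integer(cp$i); cp$j <- as.integer(cp$j)
    if (!is.null(cp$gauss)) cp$gauss <- lapply(cp$gauss, unlist)
    cp
  })
  mat <- function(x) if (is.null(x)) NULL else
    matrix(as.numeric(unlist(x)), ns, na, byrow = TRUE)
  td <- NULL
  if (!is.null(cfg$trans_dipoles)) {
    td <- array(0, c(ns, ns, 3))
    for (e in cfg$trans_dipoles) {
      td[e$i, e$j, ] <- td[e$j, e$i, ] <- as.numeric(unlist(e$mu))
    }
  }
  diabatic_model(ns, na, terms, couplings,
                 state_charges = mat(cfg$state_charges),
                 trans_charges = mat(cfg$trans_charges),
                 trans_dipoles = td,
                 ct_labels = as.logical(unlist(cfg$ct_labels %||% rep(FALSE, ns))),
                 atoms = as.character(unlist(cfg$atoms %||% NULL)))
}

#' Write an ensemble summary to JSON/CSV
#'
#' @param summary an `ensemble_summary`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_ensemble_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "ensemble.csv")
  utils::write.csv(summary$records, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  payload <- list(
    n_total = summary$n_total, n_valid = summary$n_valid,
    n_reactive = summary$n_reactive, n_hbond_broken = summary$n_hbond_broken)
  if (!is.null(summary$reactive))
    payload$reactive <- summary$reactive[c("percent", "margin", "k", "n")]
  if (!is.null(summary$hbond))
    payload$hbond_break <- summary$hbond[c("percent", "margin", "k", "n")]
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
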