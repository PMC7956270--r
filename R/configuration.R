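#' Molecular configuration container
#'
#' A `liq_configuration` holds one frame of a molecular system in an
#' orthorhombic periodic box: Cartesian coordinates in Angstrom, chemical
#' species, molecule membership, per-molecule type (water or methanol) and a
#' per-atom role tag that the analysis modules key on.
#'
#' Recognised roles are `water_O`, `water_H` (water: 1 oxygen + 2 hydrogens),
#' and `hydroxyl_O`, `hydroxyl_H`, `methyl_C`, `methyl_H` (methanol:
#' 1 + 1 + 1 + 3). Hydroxyl and water hydrogens are the only hydrogen-bond
#' donors; methyl hydrogens never donate.
#'
#' @param box_lengths numeric(3), box edge lengths in Angstrom (> 0).
#' @param atoms data.frame with columns `x`, `y`, `z` (Angstrom), `species`
#'   (chemical label: "O", "H" or "C"), `mol_id` (integer molecule index) and
#'   `role` (one of the six role tags).
#' @param validate logical; run the full invariant check (default TRUE).
#' @return An object of class `liq_configuration`: a list with elements
#'   `box` (numeric(3)) and `atoms` (the data.frame), plus a `mol_type`
#'   character vector named by molecule id.
#' @export
configuration <- function(box_lengths, atoms, validate = TRUE) {
  box_lengths <- as.numeric(box_lengths)
  if (length(box_lengths) == 1) box_lengths <- rep(box_lengths, 3)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  cfg <- structure(list(box = box_lengths, atoms = atoms),
                   class = "liq_configuration")
  cfg$mol_type <- infer_molecule_types(atoms)
  if (validate) validate_configuration(cfg)
  cfg
}

WATER_ROLES    <- c("water_O", "water_H")
METHANOL_ROLES <- c("hydroxyl_O", "hydroxyl_H", "methyl_C", "methyl_H")
ALL_ROLES      <- c(WATER_ROLES, METHANOL_ROLES)
ROLE_SPECIES   <- c(water_O = "O", water_H = "H", hydroxyl_O = "O",
                    hydroxyl_H = "H", methyl_C = "C", methyl_H = "H")

infer_molecule_types <- function(atoms) {
  if (nrow(atoms) == 0) return(character(0))
  w <- atoms$role %in% WATER_ROLES
  tab <- tapply(w, atoms$mol_id, all)
  out <- ifelse(as.logical(tab), "water", "methanol")
  names(out) <- names(tab)
  out
}

#' Validate a configuration's structural invariants
#'
#' Checks finiteness of coordinates, positivity of the box, and that every
#' molecule carries exactly the role multiset of a rigid water
#' (one `water_O`, two `water_H`) or methanol
#' (`hydroxyl_O`, `hydroxyl_H`, `methyl_C`, 3 x `methyl_H`).
#'
#' @param cfg a `liq_configuration`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_configuration <- function(cfg) {
  stopifnot(inherits(cfg, "liq_configuration"))
  if (length(cfg$box) != 3 || any(!is.finite(cfg$box)) || any(cfg$box <= 0))
    stop("box_lengths must be three positive finite values (orthorhombic box)")
  at <- cfg$atoms
  need <- c("x", "y", "z", "species", "mol_id", "role")
  if (!all(need %in% names(at)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (nrow(at) == 0) return(invisible(cfg))
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("all coordinates must be finite")
  bad <- setdiff(unique(at$role), ALL_ROLES)
  if (length(bad))
    stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  if (any(at$species != ROLE_SPECIES[at$role]))
    stop("species labels inconsistent with roles")
  for (m in split(at$role, at$mol_id)) {
    cnt <- table(factor(m, levels = ALL_ROLES))
    water_ok <- cnt["water_O"] == 1 && cnt["water_H"] == 2 && sum(cnt) == 3
    meoh_ok  <- cnt["hydroxyl_O"] == 1 && cnt["hydroxyl_H"] == 1 &&
      cnt["methyl_C"] == 1 && cnt["methyl_H"] == 3 && sum(cnt) == 6
    if (!water_ok && !meoh_ok)
      stop("molecule with invalid role multiset: ",
           paste(sort(m), collapse = ","))
  }
  invisible(cfg)
}

#' @export
print.liq_configuration <- function(x, ...) {
  nm <- length(unique(x$atoms$mol_id))
  nw <- sum(x$mol_type == "water")
  cat(sprintf("<liq_configuration> %d atoms, %d molecules (%d water, %d methanol)\n",
              nrow(x$atoms), nm, nw, nm - nw))
  cat(sprintf("  box: %.3f x %.3f x %.3f Angstrom\n",
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of atoms / molecules
#' @param cfg a `liq_configuration`.
#' @return integer count.
#' @export
n_atoms <- function(cfg) nrow(cfg$atoms)

#' @rdname n_atoms
#' @export
n_molecules <- function(cfg) length(unique(cfg$atoms$mol_id))

#' Wrap coordinates into the primary box
#'
#' Applies periodic wrapping so all coordinates lie in `[0, L)` per axis.
#' Analyses use minimum-image distances and are invariant to wrapping; this
#' helper exists because trajectory writers differ on whether they wrap.
#'
#' @param cfg a `liq_configuration`.
#' @return the configuration with wrapped coordinates.
#' @export
wrap_configuration <- function(cfg) {
  for (i in seq_len(3)) {
    d <- c("x", "y", "z")[i]
    cfg$atoms[[d]] <- cfg$atoms[[d]] %% cfg$box[i]
  }
  cfg
}

#' Mixture composition descriptor
#'
#' @param x_methanol methanol mole fraction in \[0, 1\].
#' @param n_molecules total number of molecules.
#' @param number_density atomic number density in atoms per cubic Angstrom
#'   (the convention of the shipped density table), or NA.
#' @return a `liq_composition` list.
#' @export
composition <- function(x_methanol, n_molecules = NA_integer_,
                        number_density = NA_real_) {
  if (x_methanol < 0 || x_methanol > 1)
    stop("x_methanol must lie in [0, 1]")
  structure(list(x_methanol = x_methanol, n_molecules = n_molecules,
                 number_density = number_density),
            class = "liq_composition")
}

#' Atoms per molecule at a given methanol fraction
#' @param x_methanol methanol mole fraction.
#' @return mean atoms per molecule: 3(1-x) + 6x.
#' @export
atoms_per_molecule <- function(x_methanol) 3 * (1 - x_methanol) + 6 * x_methanol

#' Per-species atomic concentrations of a mixture
#'
#' Fractions of each atomic species class among all atoms, distinguishing
#' water hydrogen, hydroxyl hydrogen and methyl hydrogen (their neutron
#' weights may differ under selective deuteration). Oxygen is aggregated
#' across water and methanol. Fractions sum to one.
#'
#' @param comp a `liq_composition` (or a bare mole fraction).
#' @return named numeric vector with entries `O`, `H_water`, `H_hydroxyl`,
#'   `H_methyl`, `C` (zero entries dropped).
#' @export
atomic_concentrations <- function(comp) {
  x <- if (inherits(comp, "liq_composition")) comp$x_methanol else comp
  if (x < 0 || x > 1) stop("x_methanol must lie in [0, 1]")
  apm <- atoms_per_molecule(x)
  c_full <- c(O = ((1 - x) + x) / apm,
              H_water = 2 * (1 - x) / apm,
              H_hydroxyl = x / apm,
              H_methyl = 3 * x / apm,
              C = x / apm)
  c_full[c_full > 0]
}

#' Concentrations resolved by atom role (water vs methanol oxygen separate)
#'
#' Like [atomic_concentrations()] but keeps `water_O` and `hydroxyl_O`
#' separate, matching the role labels that partial radial distribution
#' functions are computed over.
#'
#' @param comp a `liq_composition` or mole fraction.
#' @return named numeric vector over the six atom roles (zeros dropped).
#' @export
role_concentrations <- function(comp) {
  x <- if (inherits(comp, "liq_composition")) comp$x_methanol else comp
  apm <- atoms_per_molecule(x)
  c_full <- c(water_O = (1 - x) / apm, water_H = 2 * (1 - x) / apm,
              hydroxyl_O = x / apm, hydroxyl_H = x / apm,
              methyl_C = x / apm, methyl_H = 3 * x / apm)
  c_full[c_full > 0]
}

#' Look up a shipped mixture number density
#'
#' Reads the packaged pressure/composition table of atomic number densities
#' (from NpT simulation of water-methanol mixtures) and returns the density
#' at the requested composition and pressure.
#'
#' @param x_methanol mole fraction, one of 0, 0.1, ..., 1.0.
#' @param pressure_GPa one of 0.15, 0.4, 0.8, 1.2.
#' @return number density in atoms per cubic Angstrom.
#' @export
lookup_density <- function(x_methanol, pressure_GPa) {
  tab <- load_density_table()
  hit <- abs(tab$x_methanol - x_methanol) < 1e-9 &
    abs(tab$pressure_GPa - pressure_GPa) < 1e-9
  if (!any(hit))
    stop("no tabulated density for x = ", x_methanol,
         ", p = ", pressure_GPa, " GPa")
  tab$number_density[hit][1]
}

#' Load the shipped density table
#' @return data.frame with columns x_methanol, pressure_GPa, number_density,
#'   comment.
#' @export
load_density_table <- function() {
  path <- system.file("extdata", "number_densities.csv", package = "liqstruct")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Trajectory: an ordered list of configurations
#'
#' @param frames list of `liq_configuration` objects sharing topology.
#' @param labels optional per-frame tags (time, pressure).
#' @return a `liq_trajectory` object.
#' @export
trajectory <- function(frames, labels = NULL) {
  if (inherits(frames, "liq_configuration")) frames <- list(frames)
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  n <- vapply(frames, n_atoms, integer(1))
  if (length(unique(n)) != 1)
    stop("all frames must share the same atom count")
  structure(list(frames = frames, labels = labels), class = "liq_trajectory")
}

as_trajectory <- function(x) {
  if (inherits(x, "liq_trajectory")) x else trajectory(x)
}
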