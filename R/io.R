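#' Read a molecular configuration from a text file
#'
#' Two dialects are supported. `extended-xyz` files carry the box on the
#' comment line (`Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`) and per-atom columns
#' `species x y z mol role`. `gro` files are fixed-column GROMACS-style text;
#' coordinates are stored in nm and converted to Angstrom on read, and atom
#' roles are inferred from residue/atom names via the packaged mapping table
#' (see `system.file("extdata", "atom_roles.yaml", package = "liqstruct")`).
#'
#' Molecules are defined by the explicit molecule column (XYZ) or residue
#' numbering (GRO); no bond perception from distances is ever attempted.
#' Only orthorhombic boxes are supported; triclinic lattices error.
#'
#' @param path file path.
#' @param format "extended-xyz" or "gro"; default guesses from the extension.
#' @return a validated `liq_configuration`.
#' @export
read_configuration <- function(path, format = c("auto", "extended-xyz", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "extended-xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "extended-xyz") read_extxyz(lines, path) else read_gro(lines, path)
}

read_extxyz <- function(lines, path) {
  if (length(lines) < 2) stop("parse error at line 1: truncated file ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0)
    stop("parse error at line 1: expected atom count, got '", lines[1], "'")
  comment <- lines[2]
  lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(lat) < 2)
    stop("parse error at line 2: missing Lattice=\"...\" entry")
  lv <- suppressWarnings(as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]]))
  if (length(lv) != 9 || any(is.na(lv)))
    stop("parse error at line 2: Lattice must contain 9 numbers")
  M <- matrix(lv, nrow = 3, byrow = TRUE)
  if (any(abs(M[upper.tri(M) | lower.tri(M)]) > 1e-10))
    stop("unsupported feature: triclinic lattice (orthorhombic boxes only)")
  box <- diag(M)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("structural error: header declares ", n, " atoms but file lists ",
         length(body))
  if (n == 0)
    return(configuration(box, data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0), species = character(0),
                                         mol_id = integer(0), role = character(0))))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("parse error at line ", which(nf < 6)[1] + 2,
         ": expected 'species x y z mol role'")
  tab <- do.call(rbind, fields)
  xyz <- suppressWarnings(apply(tab[, 2:4, drop = FALSE], 2, as.numeric))
  xyz <- matrix(xyz, ncol = 3)
  if (any(is.na(xyz)))
    stop("parse error: non-numeric coordinate at line ",
         which(rowSums(is.na(xyz)) > 0)[1] + 2)
  mol <- suppressWarnings(as.integer(tab[, 5]))
  if (any(is.na(mol))) stop("parse error: non-integer molecule id")
  role <- tab[, 6]
  bad <- setdiff(unique(role), ALL_ROLES)
  if (length(bad)) stop("typing error: unknown role(s): ",
                        paste(bad, collapse = ", "))
  configuration(box, data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                species = ROLE_SPECIES[role], mol_id = mol,
                                role = role, stringsAsFactors = FALSE))
}

#' Write a configuration to disk
#'
#' Inverse of [read_configuration()]; round-trips positions to at least six
#' significant digits and typing exactly (GRO files store nm to 0.001 nm
#' fixed precision, i.e. 0.01 Angstrom; use extended-xyz when full precision
#' matters).
#'
#' @param cfg a `liq_configuration`.
#' @param path output path.
#' @param format "extended-xyz" or "gro".
#' @return `path`, invisibly.
#' @export
write_configuration <- function(cfg, path,
                                format = c("auto", "extended-xyz", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "extended-xyz"
  validate_configuration(cfg)
  if (format == "extended-xyz") write_extxyz(cfg, path) else write_gro(cfg, path)
  invisible(path)
}

write_extxyz <- function(cfg, path) {
  at <- cfg$atoms
  header <- c(
    as.character(nrow(at)),
    sprintf('Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" Properties=species:S:1:pos:R:3:mol:I:1:role:S:1',
            cfg$box[1], cfg$box[2], cfg$box[3]))
  rows <- if (nrow(at)) sprintf("%-2s %16.8f %16.8f %16.8f %6d %s",
                                at$species, at$x, at$y, at$z, at$mol_id,
                                at$role) else character(0)
  writeLines(c(header, rows), path)
}

# role -> (resname, atomname) used on GRO write; the read mapping in
# atom_roles.yaml accepts these names back.
GRO_NAMES <- list(
  water_O    = c("SOL", "OW"),
  water_H    = c("SOL", "HW"),   # numbered HW1/HW2 per molecule
  hydroxyl_O = c("MET", "O"),
  hydroxyl_H = c("MET", "HO"),
  methyl_C   = c("MET", "C"),
  methyl_H   = c("MET", "H"))   # numbered H1..H3

write_gro <- function(cfg, path) {
  at <- cfg$atoms
  lines <- c("liqstruct configuration", as.character(nrow(at)))
  if (nrow(at)) {
    ord <- order(at$mol_id, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    resid <- match(at$mol_id, unique(at$mol_id))
    resname <- vapply(at$role, function(r) GRO_NAMES[[r]][1], character(1))
    aname <- vapply(at$role, function(r) GRO_NAMES[[r]][2], character(1))
    # number repeated hydrogens within each molecule (HW1/HW2, H1..H3)
    for (m in unique(resid)) {
      i <- which(resid == m)
      for (base in c("HW", "H")) {
        j <- i[aname[i] == base]
        if (length(j)) aname[j] <- paste0(base, seq_along(j))
      }
    }
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resid %% 100000, resname, aname,
                    seq_len(nrow(at)) %% 100000,
                    at$x / 10, at$y / 10, at$z / 10)
    lines <- c(lines, body)
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f",
                            cfg$box[1] / 10, cfg$box[2] / 10, cfg$box[3] / 10))
  writeLines(lines, path)
}

load_role_map <- function() {
  path <- system.file("extdata", "atom_roles.yaml", package = "liqstruct")
  yaml::read_yaml(path)
}

read_gro <- function(lines, path) {
  if (length(lines) < 3) stop("parse error at line 1: truncated GRO file ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0)
    stop("parse error at line 2: expected atom count, got '", lines[2], "'")
  if (length(lines) < 3 + n)
    stop("structural error: header declares ", n, " atoms but file has ",
         max(0, length(lines) - 3))
  boxline <- trimws(lines[3 + n])
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  if (length(bv) < 3 || any(is.na(bv[1:3])))
    stop("parse error at line ", 3 + n, ": expected box vector")
  if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-10))
    stop("unsupported feature: triclinic box (orthorhombic only)")
  box <- bv[1:3] * 10  # nm -> Angstrom
  rmap <- load_role_map()
  res_group <- character(0)
  for (g in names(rmap))
    res_group[toupper(rmap[[g]]$residues)] <- g
  if (n == 0)
    return(configuration(box, data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0), species = character(0),
                                         mol_id = integer(0), role = character(0))))
  body <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(body, 1, 5)))
  resname <- toupper(trimws(substr(body, 6, 10)))
  aname <- toupper(trimws(substr(body, 11, 15)))
  x <- suppressWarnings(as.numeric(substr(body, 21, 28))) * 10
  y <- suppressWarnings(as.numeric(substr(body, 29, 36))) * 10
  z <- suppressWarnings(as.numeric(substr(body, 37, 44))) * 10
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("parse error at line ", bad[1] + 2, " of ", path)
  role <- character(n)
  for (i in seq_len(n)) {
    g <- res_group[resname[i]]
    if (is.na(g)) stop("typing error: unknown residue name '", resname[i], "'")
    amap <- rmap[[g]]$atoms
    nm <- aname[i]
    r <- amap[[nm]]
    if (is.null(r)) {  # strip trailing digits (H1 -> H, HW2 -> HW)
      stem <- sub("[0-9]+$", "", nm)
      r <- amap[[stem]]
      if (is.null(r) && stem == "HW") r <- amap[["HW1"]]
    }
    if (is.null(r))
      stop("typing error: unknown atom name '", aname[i], "' in residue '",
           resname[i], "'")
    role[i] <- r
  }
  # residue numbers wrap at 100000 in fixed columns; rebuild ids from blocks
  newmol <- c(TRUE, resid[-1] != resid[-n])
  mol_id <- cumsum(newmol)
  configuration(box, data.frame(x = x, y = y, z = z,
                                species = ROLE_SPECIES[role],
                                mol_id = mol_id, role = role,
                                stringsAsFactors = FALSE))
}
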