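# File formats: GRO coordinates (hand-written fixed-width reader/writer;
# positions in nm), species->charge tables as two-column TSV, stack
# parameters as flat YAML, scan tables as commented TSV, pore summaries as
# JSON. PDB import goes through bio3d.

# species label -> at-most-5-character GRO residue name
.species_resname <- c(ION = "ION", HEAD_POPS = "POPS", HEAD_PIP2 = "PIP2",
                      HEAD_NEUTRAL = "HEADN", HEAD_CHARGED = "HEADC",
                      WATER_MARK = "WAT", COMP = "COMP")

resname_for <- function(species) {
  out <- unname(.species_resname[species])
  out[is.na(out)] <- substr(species[is.na(out)], 1, 5)
  out
}

species_for_resname <- function(resname) {
  rev_map <- stats::setNames(names(.species_resname),
                             unname(.species_resname))
  out <- unname(rev_map[resname])
  out[is.na(out)] <- resname[is.na(out)]
  out
}

#' Write a configuration as a GRO file with a charge table
#'
#' Z coordinates are shifted from the package's centred convention to the
#' GRO convention (origin at the box corner). A companion two-column TSV
#' maps each residue name to its per-particle charge; species whose
#' particles carry unequal charges cannot be expressed and raise an error.
#'
#' @param config a [pseudo_configuration()].
#' @param path output `.gro` path.
#' @param charge_table_path output TSV path; default replaces the extension
#'   with `_charges.tsv`.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(config, path,
                      charge_table_path = NULL,
                      title = "memvolt configuration") {
  stopifnot(inherits(config, "pseudo_configuration"))
  if (is.null(charge_table_path))
    charge_table_path <- sub("\\.gro$", "", path) |> paste0("_charges.tsv")
  res <- resname_for(config$species)
  n <- nrow(config$positions)
  z <- config$positions[, 3] + config$box[3] / 2
  idx <- seq_len(n) %% 100000L
  lines <- c(title, format(n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     idx, res, substr(res, 1, 5), idx,
                     config$positions[, 1], config$positions[, 2], z),
             sprintf("%10.5f%10.5f%10.5f",
                     config$box[1], config$box[2], config$box[3]))
  writeLines(lines, path)
  qt <- unique(data.frame(species = res, charge = config$charges))
  if (anyDuplicated(qt$species))
    stop("species with non-uniform charges cannot be written to a ",
         "charge table: ", paste(unique(qt$species[duplicated(qt$species)]),
                                 collapse = ", "))
  utils::write.table(qt, charge_table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a species-to-charge table
#'
#' @param path two-column TSV (`species`, `charge`).
#' @return named numeric vector of charges, e.
#' @export
read_charge_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("species", "charge") %in% names(tab)))
  stats::setNames(tab$charge, tab$species)
}

#' Read a GRO or PDB coordinate file into a configuration
#'
#' GRO files are parsed directly (fixed-width, positions in nm); PDB files
#' go through [bio3d::read.pdb()] (positions converted from Angstrom to
#' nm; the box is taken from the CRYST1 record when present, otherwise from
#' the coordinate extent). Charges are looked up per residue name in the
#' charge table; residues missing from the table get zero charge.
#'
#' @param path coordinate file (`.gro` or `.pdb`).
#' @param charges named charge vector (from [read_charge_table()]) or path
#'   to a charge table TSV; `NULL` means all charges zero.
#' @return a [pseudo_configuration()] (Z re-centred on the box mid-plane).
#' @export
read_configuration <- function(path, charges = NULL) {
  if (is.character(charges) && length(charges) == 1L)
    charges <- read_charge_table(charges)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[2L]))
    at <- lines[3L:(2L + n)]
    res <- trimws(substr(at, 6, 10))
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    box <- as.numeric(strsplit(trimws(lines[3L + n]), "\\s+")[[1L]])[1:3]
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    res <- pdb$atom$resid
    x <- pdb$atom$x / 10; y <- pdb$atom$y / 10; z <- pdb$atom$z / 10
    cr <- tryCatch(pdb$cryst1$abc / 10, error = function(e) NULL)
    box <- if (!is.null(cr) && all(is.finite(cr)) && all(cr > 0)) cr
    else c(max(x) - min(x), max(y) - min(y), max(z) - min(z))
  } else stop("unsupported coordinate format: .", ext)
  q <- if (is.null(charges)) rep(0, length(res))
  else {
    qq <- unname(charges[res]); qq[is.na(qq)] <- 0; qq
  }
  pseudo_configuration(cbind(x, y, z - box[3] / 2), q,
                       species_for_resname(res), box)
}

#' Write a trajectory as numbered GRO frames with a YAML sidecar
#'
#' @param trajectory a [membrane_trajectory()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return character vector of frame paths, invisibly.
#' @export
write_trajectory_gro <- function(trajectory, dir, prefix = "frame") {
  stopifnot(inherits(trajectory, "membrane_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(trajectory$frames))
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%04d.gro", prefix, i))
    write_gro(f, paths[i],
              charge_table_path = file.path(dir,
                                            paste0(prefix, "_charges.tsv")),
              title = sprintf("t = %g ns", f$frame_time))
  }
  side <- list(frames = length(trajectory$frames),
               times_ns = trajectory$times)
  if (!is.null(trajectory$schedule))
    side$pore_schedule <- trajectory$schedule[c("template", "t_open", "r0")]
  yaml::write_yaml(side, file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(paths)
}

#' Write / read layer-stack parameters as flat YAML
#'
#' @param stack a [layer_stack()].
#' @param path YAML file path.
#' @return `write_stack_yaml` returns `path` invisibly; `read_stack_yaml`
#'   returns a [layer_stack()].
#' @export
write_stack_yaml <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  yaml::write_yaml(unclass(stack)[c("rho1", "rho2", "rho3", "rho_m1",
                                    "rho_m2", "H_L", "H_m", "D", "eps_r")],
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_stack_yaml
#' @export
read_stack_yaml <- function(path) {
  do.call(layer_stack, yaml::read_yaml(path))
}

#' Write a scan result as a commented TSV
#'
#' Plain tab-separated table preceded by `#` comment lines recording units,
#' the charge-closure policy and the package version.
#'
#' @param scan a `scan_result` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  hdr <- c(sprintf("# memvolt %s scan: %s",
                   as.character(utils::packageVersion("memvolt")),
                   attr(scan, "scan") %||% "scan"),
           "# units: D nm, dV volts, T ns, pops_pct percent")
  if (!is.null(attr(scan, "policy")))
    hdr <- c(hdr, paste0("# policy: ", attr(scan, "policy")))
  if (!is.null(attr(scan, "D_critical")))
    hdr <- c(hdr, paste0("# D_critical_nm: ",
                         format(attr(scan, "D_critical"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(as.data.frame(scan), con, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Write a pore analysis summary as JSON
#'
#' @param summary named list (e.g. counts, formation time, fate label,
#'   Gaussian fit parameters).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pore_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
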