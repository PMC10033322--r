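#' @keywords internal
"_PACKAGE"

## Gas constant in kJ mol^-1 K^-1, used by every free-energy transform.
RGAS <- 0.0083145

ROLE_LEVELS <- c("protein", "lipid", "water", "ion", "other")

SUBROLE_LEVELS <- c("backbone", "sidechain", "carbonyl_O", "phosphate",
                    "choline", "ester_O", "water_O", "K", "Cl", "other")

## Which subroles are legal under which role.
ROLE_COMPAT <- list(
  protein = c("backbone", "sidechain", "carbonyl_O", "other"),
  lipid   = c("phosphate", "choline", "ester_O", "carbonyl_O", "other"),
  water   = c("water_O", "other"),
  ion     = c("K", "Cl"),
  other   = "other"
)

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE",
                 "PRO", "SER", "THR", "TRP", "TYR", "VAL")

WATER_RESNAMES <- c("HOH", "SOL", "TIP3", "WAT", "SPC")
LIPID_RESNAMES <- c("POPC", "POPE", "DOPC", "DPPC", "LIP")

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, K = 39.098, CL = 35.45,
                   NA. = 22.990, X = 0)

#' Guess the chemical element from an atom name
#'
#' Strips digits and primes, then matches two-letter elements (Cl, Na)
#' before falling back to the leading letter.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols ("X" if unknown).
#' @keywords internal
guess_element <- function(name) {
  clean <- toupper(gsub("[0-9'\"*]", "", trimws(name)))
  out <- character(length(clean))
  two <- substr(clean, 1, 2)
  out[two == "CL"] <- "Cl"
  out[clean == "NA"] <- "Na"
  rest <- out == ""
  first <- substr(clean[rest], 1, 1)
  first[!first %in% c("H", "C", "N", "O", "P", "S", "K")] <- "X"
  out[rest] <- first
  out
}

atom_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- ATOMIC_MASSES[key]
  m[is.na(m)] <- 0
  unname(m)
}

## Rule table mapping (residue name, atom name) -> (role, subrole).
## Unknown combinations are tagged other/other with a warning upstream.
assign_role <- function(name, residue_name) {
  name <- toupper(trimws(name))
  resn <- toupper(trimws(residue_name))
  n <- length(name)
  role <- rep("other", n)
  subrole <- rep("other", n)

  is_water <- resn %in% WATER_RESNAMES
  role[is_water] <- "water"
  subrole[is_water & name %in% c("OW", "O", "OH2")] <- "water_O"

  is_k <- resn %in% c("K", "POT", "K+") & name %in% c("K", "POT", "K+")
  is_cl <- resn %in% c("CL", "CLA", "CL-") & name %in% c("CL", "CLA", "CL-")
  role[is_k | is_cl] <- "ion"
  subrole[is_k] <- "K"
  subrole[is_cl] <- "Cl"

  is_lip <- resn %in% LIPID_RESNAMES
  role[is_lip] <- "lipid"
  subrole[is_lip & name %in% c("P", "O11", "O12", "O13", "O14")] <- "phosphate"
  subrole[is_lip & name %in% c("N", "C11", "C12", "C13", "C14", "C15")] <- "choline"
  subrole[is_lip & name %in% c("O21", "O31")] <- "ester_O"
  subrole[is_lip & name %in% c("O22", "O32")] <- "carbonyl_O"

  is_prot <- resn %in% AMINO_ACIDS
  role[is_prot] <- "protein"
  subrole[is_prot] <- "sidechain"
  subrole[is_prot & name %in% c("N", "CA", "C", "H", "HN", "HA")] <- "backbone"
  ## backbone carbonyl oxygen kept distinguishable for ion-coordination work
  subrole[is_prot & name %in% c("O", "OXT", "OT1", "OT2")] <- "carbonyl_O"

  list(role = role, subrole = subrole)
}

#' Construct an atom topology table
#'
#' The topology is a plain \code{data.frame} (class \code{edgepore_topology})
#' with one row per atom: \code{atom_index}, \code{name}, \code{element},
#' \code{residue_number}, \code{residue_name}, \code{chain_id}, \code{role},
#' \code{subrole}.  Roles classify atoms into protein/lipid/water/ion for all
#' downstream selections; subroles refine them (phosphate, choline, ester and
#' carbonyl oxygens, water oxygen, K, Cl, protein backbone/side chain).
#'
#' @param name atom names.
#' @param residue_name residue names (3-letter codes for protein, POPC/SOL/...).
#' @param residue_number integer residue numbers.
#' @param chain_id single-character chain identifiers.
#' @param atom_index unique integer atom indices (default 0-based sequence).
#' @param element element symbols; guessed from names when omitted.
#' @param role,subrole role tags; derived from the shipping rule table when
#'   omitted.  Atoms that match no rule are tagged \code{other} with a warning
#'   (never dropped).
#' @param warn_unknown warn about atoms tagged \code{other}?
#' @return an \code{edgepore_topology} data frame.
#' @export
topology <- function(name, residue_name, residue_number, chain_id = "A",
                     atom_index = NULL, element = NULL,
                     role = NULL, subrole = NULL, warn_unknown = TRUE) {
  n <- length(name)
  stopifnot(length(residue_name) == n, length(residue_number) == n)
  chain_id <- rep_len(as.character(chain_id), n)
  if (is.null(atom_index)) atom_index <- seq_len(n) - 1L
  if (anyDuplicated(atom_index))
    stop("atom_index values must be unique within a topology")
  if (is.null(element)) element <- guess_element(name)
  if (is.null(role) || is.null(subrole)) {
    rs <- assign_role(name, residue_name)
    if (is.null(role)) role <- rs$role
    if (is.null(subrole)) subrole <- rs$subrole
  }
  role <- rep_len(role, n); subrole <- rep_len(subrole, n)
  bad <- !role %in% ROLE_LEVELS | !subrole %in% SUBROLE_LEVELS
  if (any(bad))
    stop("unknown role/subrole tag: ",
         paste(unique(paste(role[bad], subrole[bad], sep = "/")), collapse = ", "))
  ok <- mapply(function(r, s) s %in% ROLE_COMPAT[[r]], role, subrole)
  if (!all(ok))
    stop("incompatible role/subrole combination: ",
         paste(unique(paste(role[!ok], subrole[!ok], sep = "/")), collapse = ", "))
  if (warn_unknown && any(role == "other"))
    warning(sum(role == "other"),
            " atom(s) matched no role rule and were tagged 'other'")
  out <- data.frame(atom_index = as.integer(atom_index),
                    name = as.character(name),
                    element = as.character(element),
                    residue_number = as.integer(residue_number),
                    residue_name = as.character(residue_name),
                    chain_id = chain_id,
                    role = role, subrole = subrole,
                    stringsAsFactors = FALSE)
  class(out) <- c("edgepore_topology", "data.frame")
  out
}

#' @export
print.edgepore_topology <- function(x, ...) {
  cat(sprintf("<edgepore_topology> %d atoms; roles: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = " ")))
  invisible(x)
}

#' Select atoms from a topology
#'
#' Deterministic, order-preserving predicate selection.  All supplied filters
#' are intersected; the return value is a strictly increasing vector of row
#' positions (1-based) suitable for indexing coordinates.  Compose selections
#' with \code{union()} / \code{intersect()}.
#'
#' @param top an \code{edgepore_topology}.
#' @param role,subrole role/subrole filters (character vectors).
#' @param residue integer vector of residue numbers (e.g. \code{13:16} for the
#'   HHQK domain).
#' @param chain chain id filter.
#' @param name atom-name filter.
#' @param element element filter; use \code{heavy = TRUE} to drop hydrogens.
#' @param heavy if TRUE, restrict to non-hydrogen atoms.
#' @return integer vector of row positions (possibly empty; never an error).
#' @export
atom_select <- function(top, role = NULL, subrole = NULL, residue = NULL,
                        chain = NULL, name = NULL, element = NULL,
                        heavy = FALSE) {
  stopifnot(nrow(top) > 0)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(role))     keep <- keep & top$role %in% role
  if (!is.null(subrole))  keep <- keep & top$subrole %in% subrole
  if (!is.null(residue))  keep <- keep & top$residue_number %in% residue
  if (!is.null(chain))    keep <- keep & top$chain_id %in% chain
  if (!is.null(name))     keep <- keep & top$name %in% name
  if (!is.null(element))  keep <- keep & top$element %in% element
  if (heavy)              keep <- keep & top$element != "H"
  which(keep)
}

#' Default polar-atom selection (lipid oxygens + water oxygens)
#'
#' The defect reaction coordinate counts slices occupied by at least one
#' lipid or water oxygen atom; this helper builds that selection.
#'
#' @param top an \code{edgepore_topology}.
#' @return integer vector of row positions.
#' @export
polar_selection <- function(top) {
  sort(union(atom_select(top, role = "lipid", element = "O"),
             atom_select(top, role = "water", subrole = "water_O")))
}
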