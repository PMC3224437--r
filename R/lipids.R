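#' Parse a metabolite identifier from the targeted panel nomenclature
#'
#' Recognizes the brutto-composition naming of a targeted serum metabolomics
#' panel: diacyl-phosphatidylcholines `PC aa Cx:y`, acyl-alkyl-PCs
#' `PC ae Cx:y`, lyso-PCs `lysoPC a Cx:y`, sphingomyelins `SM Cx:y` and
#' hydroxy-sphingomyelins `SM (OH) Cx:y`, acyl-carnitines `Cx:y-carn` with
#' hydroxy (`-OH-carn`), dicarboxy (`-DC-carn`) and methyl-dicarboxy
#' (`-M-DC-carn`) variants, amino acids by three-letter name (plus `xLeu`
#' for the isobaric Leu/Ile pair and `Orn`), and the hexose pool `H1`.
#' `x` counts the summed side-chain carbon atoms, `y` the summed double
#' bonds; for two-residue lipids (diacyl- and acyl-alkyl-PCs) the sums run
#' over both fatty acid residues.
#'
#' @param id metabolite identifier string.
#' @return object of class `lipid_annotation`: list with `id`, `class`,
#'   `carbons`, `double_bonds`, `residues` (2 for diacyl/acyl-alkyl-PCs,
#'   1 for lyso-PCs, sphingomyelins and carnitines, NA otherwise).
#' @examples
#' parse_metabolite_name("PC aa C38:4")
#' parse_metabolite_name("lysoPC a C16:0")
#' @export
parse_metabolite_name <- function(id) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  pats <- list(
    list(re = "^PC aa C([0-9]+):([0-9]+)$", class = "diacyl-PC", residues = 2L),
    list(re = "^PC ae C([0-9]+):([0-9]+)$", class = "acyl-alkyl-PC", residues = 2L),
    list(re = "^lysoPC a C([0-9]+):([0-9]+)$", class = "lyso-PC", residues = 1L),
    list(re = "^SM \\(OH\\) C([0-9]+):([0-9]+)$", class = "hydroxy-sphingomyelin",
         residues = 1L),
    list(re = "^SM C([0-9]+):([0-9]+)$", class = "sphingomyelin", residues = 1L),
    list(re = "^C([0-9]+):([0-9]+)-M-DC-carn$",
         class = "methyl-dicarboxy-acylcarnitine", residues = 1L),
    list(re = "^C([0-9]+):([0-9]+)-DC-carn$", class = "dicarboxy-acylcarnitine",
         residues = 1L),
    list(re = "^C([0-9]+):([0-9]+)-OH-carn$", class = "hydroxy-acylcarnitine",
         residues = 1L),
    list(re = "^C([0-9]+):([0-9]+)-carn$", class = "acyl-carnitine", residues = 1L)
  )
  for (p in pats) {
    m <- regmatches(id, regexec(p$re, id))[[1]]
    if (length(m) == 3) {
      return(new_lipid_annotation(id, p$class,
                                  as.integer(m[2]), as.integer(m[3]),
                                  p$residues))
    }
  }
  if (id %in% amino_acid_ids()) {
    return(new_lipid_annotation(id, "amino acid", NA_integer_, NA_integer_,
                                NA_integer_))
  }
  if (id %in% c("H1", "Hexose")) {
    return(new_lipid_annotation(id, "hexose", NA_integer_, NA_integer_,
                                NA_integer_))
  }
  stop("cannot parse metabolite identifier '", id, "'")
}

new_lipid_annotation <- function(id, class, carbons, double_bonds, residues) {
  if (!is.na(carbons) && (carbons < 0 || double_bonds < 0)) {
    stop("carbon and double-bond counts must be >= 0 in '", id, "'")
  }
  structure(
    list(id = id, class = class, carbons = carbons,
         double_bonds = double_bonds, residues = residues),
    class = "lipid_annotation"
  )
}

amino_acid_ids <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Gln", "Glu", "Gly", "His", "Met", "Orn",
    "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val", "xLeu", "Lys")
}

#' Parse a whole metabolite panel
#'
#' @param ids character vector of metabolite identifiers.
#' @return data frame with columns `id`, `class`, `carbons`, `double_bonds`,
#'   `residues`.
#' @export
parse_panel <- function(ids) {
  rows <- lapply(ids, function(x) {
    a <- parse_metabolite_name(x)
    data.frame(id = a$id, class = a$class, carbons = a$carbons,
               double_bonds = a$double_bonds, residues = a$residues,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# projection domain of a metabolite class on the pathway model
class_domain <- function(class) {
  biosynth <- c("diacyl-PC", "acyl-alkyl-PC", "lyso-PC", "sphingomyelin",
                "hydroxy-sphingomyelin")
  beta <- c("acyl-carnitine", "hydroxy-acylcarnitine",
            "dicarboxy-acylcarnitine", "methyl-dicarboxy-acylcarnitine")
  ifelse(class %in% biosynth, "biosynthesis",
         ifelse(class %in% beta, "beta_oxidation", NA_character_))
}
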