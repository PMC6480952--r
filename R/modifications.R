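#' Bundled modified-residue table
#'
#' Maps three-letter chemical-component codes of commonly observed modified
#' ribonucleotides to their unmodified parent letter.  The table is a
#' curated offline snapshot of the parent-component assignments in the wwPDB
#' chemical component dictionary (as exposed by PDBeChem); bundling it keeps
#' parsing reproducible and download-free.  A refresh script that rebuilds
#' the table from the dictionary is installed under
#' \code{inst/scripts/refresh_modifications.R}.
#'
#' The four standard codes map to themselves.  Unknown codes are handled by
#' [normalize_residue()].
#'
#' @param extra named character vector of additional code -> parent entries,
#'   which override bundled ones.
#' @return named character vector: names are 3-letter codes, values parent
#'   letters in \code{A,C,G,U}.
#' @export
#' @examples
#' modification_table()[["PSU"]]  # pseudouridine -> "U"
modification_table <- function(extra = character()) {
  tab <- c(
    # standard residues map to themselves
    A = "A", C = "C", G = "G", U = "U",
    # adenosine derivatives
    `1MA` = "A",  # 1-methyladenosine
    `2MA` = "A",  # 2-methyladenosine
    `6MZ` = "A",  # N6-methyladenosine
    A2M   = "A",  # 2'-O-methyladenosine
    MA6   = "A",  # N6,N6-dimethyladenosine
    MIA   = "A",  # 2-methylthio-N6-isopentenyladenosine
    T6A   = "A",  # N6-threonylcarbamoyladenosine
    I     = "A",  # inosine (deaminated adenosine)
    AMP = "A", ADP = "A", ATP = "A",
    # guanosine derivatives
    `1MG` = "G",  # 1-methylguanosine
    `2MG` = "G",  # N2-methylguanosine
    M2G   = "G",  # N2,N2-dimethylguanosine
    `7MG` = "G",  # 7-methylguanosine
    G7M   = "G",  # 7-methylguanosine-5'-monophosphate
    OMG   = "G",  # 2'-O-methylguanosine
    QUO   = "G",  # queuosine
    YG    = "G",  # wybutosine
    YYG   = "G",  # hydroxywybutosine
    GDP = "G", GTP = "G", GNP = "G",
    # cytidine derivatives
    `5MC` = "C",  # 5-methylcytidine
    OMC   = "C",  # 2'-O-methylcytidine
    `4SC` = "C",  # 4-thiocytidine
    # uridine derivatives
    PSU   = "U",  # pseudouridine
    H2U   = "U",  # dihydrouridine
    DHU   = "U",  # dihydrouridine (legacy code)
    `5MU` = "U",  # 5-methyluridine (ribothymidine)
    OMU   = "U",  # 2'-O-methyluridine
    `4SU` = "U",  # 4-thiouridine
    UR3   = "U",  # 3-methyluridine
    `5BU` = "U",  # 5-bromouridine
    `5FU` = "U"   # 5-fluorouridine
  )
  if (length(extra)) tab[names(extra)] <- extra
  tab
}
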