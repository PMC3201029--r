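#' The standard amino acid alphabet
#'
#' The 20 standard one-letter residue codes in the canonical NCBI matrix
#' order (A R N D C Q E G H I L K M F P S T W Y V). Every 20x20 table in the
#' package is indexed in this order; it is the single source of truth that
#' keeps matrix rows and columns from drifting.
#'
#' @return Character vector of 20 uppercase one-letter codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() .AA

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Non-standard residue codes accepted in input sequences. During matrix
# derivation, columns containing them are skipped; during alignment they
# score via the fallback matrix's ambiguity columns when present, else 0.
.AA_AMBIG <- c("B", "Z", "X", "U", "O", "J")

.AA_VALID <- c(.AA, .AA_AMBIG)

aa_index <- function(letters) match(letters, .AA)

# split a residue/gap string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

ungap <- function(s) gsub("-", "", s, fixed = TRUE)
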