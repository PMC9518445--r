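## 15-bit architecture genome ------------------------------------------------
##
## The shared search space of both optimizers: 15 bits decode to a full
## fusion-classifier configuration.  Bit layout (0-based positions):
##   0-2   channel inclusion mask (Fp2-F4, F4-C4, C4-A1); 000 is invalid
##   3-4   time steps T        in {5, 10, 15, 25}
##   5     recurrent layers    in {1, 2}
##   6     recurrent type      in {unidirectional, bidirectional}
##   7-8   hidden units H      in {50, 100, 150, 200} (per direction)
##   9-10  dropout             in {5%, 10%, 15%, 20%}
##   11-12 dense size S        in {0, 100, 200, 300} (0 = no dense layers)
##   13-14 dense activation    in {tanh, sigmoid, relu, selu}
## Multi-bit fields read the first bit as the most significant.  The all-zero
## channel mask being the single invalid state yields 7 * 2^12 = 28,672 valid
## patterns out of 2^15.

ENC_OPTIONS <- list(
  time_steps = c(5L, 10L, 15L, 25L),
  n_layers = c(1L, 2L),
  bidirectional = c(FALSE, TRUE),
  hidden = c(50L, 100L, 150L, 200L),
  dropout = c(0.05, 0.10, 0.15, 0.20),
  dense = c(0L, 100L, 200L, 300L),
  activation = c("tanh", "sigmoid", "relu", "selu")
)

#' The genome decoding table
#'
#' Machine-readable description of the 15-bit encoding: one row per bit
#' position giving the field it belongs to and the option set the field
#' indexes into (first bit of a field = most significant). The same table is
#' shipped as `inst/extdata/encoding_table.csv` so it can be audited.
#'
#' @return A data.frame with columns `bit` (0-based), `field`, `options`.
#' @export
#' @examples
#' encoding_table()
encoding_table <- function() {
  fields <- c(rep("channel_mask", 3), rep("time_steps", 2), "n_layers",
              "bidirectional", rep("hidden", 2), rep("dropout", 2),
              rep("dense", 2), rep("activation", 2))
  opts <- vapply(fields, function(f) {
    if (f == "channel_mask") paste(CAP_CHANNELS, collapse = "|")
    else paste(ENC_OPTIONS[[f]], collapse = "|")
  }, "")
  data.frame(bit = 0:14, field = fields, options = unname(opts))
}

check_bits <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 15 || any(is.na(bits)) || any(!bits %in% 0:1))
    stopf("a genome must be exactly 15 bits of 0/1")
  bits
}

bits_to_index <- function(bits) {          # big-endian, 1-based option index
  sum(bits * 2L^rev(seq_along(bits) - 1L)) + 1L
}

index_to_bits <- function(index, width) {
  v <- index - 1L
  rev((v %/% 2L^(seq_len(width) - 1L)) %% 2L)
}

#' Model configuration for the fusion classifier
#'
#' Plain constructor for the decoded architecture parameters. Values are not
#' restricted to the genome option sets, so scaled-down configurations (e.g.
#' `hidden = 16`) can be trained directly; [encode_config()] enforces
#' membership when a genome is required.
#'
#' @param channels Logical length-3 channel inclusion mask (at least one).
#' @param time_steps Epochs per window fed to the recurrent branch.
#' @param n_layers Number of stacked recurrent layers per branch (1 or 2).
#' @param bidirectional Bidirectional recurrence?
#' @param hidden Hidden units per direction.
#' @param dropout Dropout fraction for recurrent and dense layer outputs.
#' @param dense Dense layer size `S`; 0 disables both the per-branch and the
#'   post-fusion dense layers.
#' @param activation Dense activation: `"tanh"`, `"sigmoid"`, `"relu"` or
#'   `"selu"`.
#' @return An object of class `cap_config`.
#' @export
#' @examples
#' cap_config(hidden = 16, time_steps = 5)
cap_config <- function(channels = c(TRUE, TRUE, TRUE), time_steps = 5,
                       n_layers = 1, bidirectional = TRUE, hidden = 16,
                       dropout = 0.05, dense = 0, activation = "tanh") {
  channels <- as.logical(channels)
  if (length(channels) != 3 || !any(channels))
    stopf("invalid genome/config: at least one of the 3 channels must be selected")
  if (!n_layers %in% 1:2) stopf("n_layers must be 1 or 2")
  if (!activation %in% ENC_OPTIONS$activation)
    stopf("activation must be one of %s", paste(ENC_OPTIONS$activation, collapse = ", "))
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(channels = channels, time_steps = as.integer(time_steps),
                 n_layers = as.integer(n_layers),
                 bidirectional = as.logical(bidirectional),
                 hidden = as.integer(hidden), dropout = dropout,
                 dense = as.integer(dense), activation = activation),
            class = "cap_config")
}

#' @export
print.cap_config <- function(x, ...) {
  cat("Fusion classifier configuration\n")
  cat(sprintf("  channels : %s\n", paste(CAP_CHANNELS[x$channels], collapse = ", ")))
  cat(sprintf("  recurrent: %d x %s layer(s), %d units/direction, T = %d\n",
              x$n_layers, if (x$bidirectional) "BLSTM" else "LSTM",
              x$hidden, x$time_steps))
  cat(sprintf("  dense    : %s, dropout %.0f%%\n",
              if (x$dense > 0) sprintf("S = %d (%s)", x$dense, x$activation)
              else "none", 100 * x$dropout))
  invisible(x)
}

#' Decode a 15-bit genome into a model configuration
#'
#' @param bits Integer/logical vector of 15 bits (see [encoding_table()]).
#' @return A [cap_config()] object.
#' @export
#' @examples
#' # the GA-selected optimum: 3 channels, T=10, 1 BLSTM layer, H=100,
#' # 15% dropout, S=300, sigmoid
#' decode_genome(c(1,1,1, 0,1, 0, 1, 0,1, 1,0, 1,1, 0,1))
decode_genome <- function(bits) {
  bits <- check_bits(bits)
  if (all(bits[1:3] == 0L))
    stopf("invalid genome: channel mask 000 selects no channel")
  cap_config(channels = bits[1:3] == 1L,
             time_steps = ENC_OPTIONS$time_steps[bits_to_index(bits[4:5])],
             n_layers = ENC_OPTIONS$n_layers[bits[6] + 1L],
             bidirectional = ENC_OPTIONS$bidirectional[bits[7] + 1L],
             hidden = ENC_OPTIONS$hidden[bits_to_index(bits[8:9])],
             dropout = ENC_OPTIONS$dropout[bits_to_index(bits[10:11])],
             dense = ENC_OPTIONS$dense[bits_to_index(bits[12:13])],
             activation = ENC_OPTIONS$activation[bits_to_index(bits[14:15])])
}

#' Encode a model configuration back into its 15-bit genome
#'
#' Inverse of [decode_genome()]; every field value must belong to the
#' encoding option sets.
#'
#' @param config A [cap_config()] object.
#' @return Integer vector of 15 bits.
#' @export
encode_config <- function(config) {
  stopifnot(inherits(config, "cap_config"))
  pos <- function(field, value) {
    i <- match(value, ENC_OPTIONS[[field]])
    if (is.na(i)) stopf("%s = %s is not in the encoding option set {%s}",
                        field, value, paste(ENC_OPTIONS[[field]], collapse = ", "))
    i
  }
  as.integer(c(config$channels,
    index_to_bits(pos("time_steps", config$time_steps), 2),
    pos("n_layers", config$n_layers) - 1L,
    as.integer(config$bidirectional),
    index_to_bits(pos("hidden", config$hidden), 2),
    index_to_bits(pos("dropout", config$dropout), 2),
    index_to_bits(pos("dense", config$dense), 2),
    index_to_bits(pos("activation", config$activation), 2)))
}

#' Repair an invalid genome
#'
#' Crossover and mutation can produce the all-zero channel mask; repair sets
#' one uniformly chosen channel bit, leaving valid genomes untouched.
#'
#' @param bits 15-bit vector.
#' @return A valid 15-bit genome.
#' @export
repair_genome <- function(bits) {
  bits <- check_bits(bits)
  if (all(bits[1:3] == 0L)) bits[sample.int(3, 1)] <- 1L
  bits
}

#' Draw a uniformly random valid genome
#'
#' @return 15-bit vector with a non-empty channel mask.
#' @export
random_genome <- function() {
  repair_genome(sample(0:1, 15, replace = TRUE))
}

#' Count the valid architecture encodings
#'
#' Enumerates all `2^15` bit patterns and counts those that decode (i.e.
#' have a non-empty channel mask): `7 * 2^12 = 28672`, the size of the grid
#' a full search would have to evaluate.
#'
#' @return Integer count.
#' @export
#' @examples
#' count_valid_configurations()  # 28672
count_valid_configurations <- function() {
  patterns <- 0:(2^15 - 1)
  # bits 0-2 are the most significant in this enumeration; mask 0 is invalid
  sum(patterns %/% 2^12 != 0)
}

#' Write the encoding table to a delimited text file
#'
#' @param path Output path (CSV).
#' @export
write_encoding_table <- function(path) {
  utils::write.csv(encoding_table(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
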