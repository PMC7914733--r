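## Shared helpers for the capgait test suite.

## Small two-module layout used in many unit tests.
tinyLayout <- function() {
  floorLayout(data.frame(
    module_id = c("A", "B"),
    center_x = c(0.19, 0.57), center_y = c(0.19, 0.19),
    edge = 0.38, stringsAsFactors = FALSE))
}

## Random valid message stream for a layout: k messages, sorted times,
## module times never running backwards (times are globally sorted).
randomMessages <- function(layout, k) {
  ids <- moduleTable(layout)$module_id
  data.frame(t = sort(round(runif(k, 0, 20), 3)),
             module = sample(ids, k, replace = TRUE),
             matrix(round(runif(8 * k), 4), k, 8,
                    dimnames = list(NULL, paste0("c", 1:8))),
             stringsAsFactors = FALSE)
}

## Quadratic-rebuild oracle: the state after message i computed from
## scratch by folding applyMessage over messages 1..i.
rebuildStateAt <- function(layout, messages, i) {
  st <- initState(layout)
  for (j in seq_len(i)) {
    st <- applyMessage(st, sensorMessage(
      messages$t[j], messages$module[j],
      as.numeric(messages[j, paste0("c", 1:8)])))
  }
  st
}

## Reconstruct the per-field capacitances valid at time tQuery from an
## emitted message stream (last message per module at or before tQuery).
reconstructAt <- function(layout, messages, tQuery) {
  st <- initState(layout)
  sel <- which(messages$t <= tQuery + 1e-9)
  for (j in sel) {
    st <- applyMessage(st, sensorMessage(
      messages$t[j], messages$module[j],
      as.numeric(messages[j, paste0("c", 1:8)])))
  }
  stateEntries(st)$c
}

## A SensorState built directly from field positions and capacitances
## (single synthetic module ids, for transform tests).
sparseFixture <- function(x, y, c) data.frame(x = x, y = y, c = c)
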