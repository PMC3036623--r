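#!/usr/bin/env Rscript
# Thin shell entry point for the boundscan package.
suppressPackageStartupMessages(library(boundscan))
quit(save = "no", status = boundscan_run())
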