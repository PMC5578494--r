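>miR162a plant mature miRNA, 5'->3'
UCGAUAAACCUCUGCAUCCAG
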