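line_item,annual_amount
administration,120000
security,36000
laundry,24000
catering,60000
utilities,48000
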