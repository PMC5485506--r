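"state","rate"
"localized_Glt7",0.005
"localized_Geq7",0.015
"localized_Ggt7",0.04
"regional_Glt7",0.02
"regional_Geq7",0.05
"regional_Ggt7",0.1
"distant_Glt7",0.2
"distant_Geq7",0.25
"distant_Ggt7",0.3
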