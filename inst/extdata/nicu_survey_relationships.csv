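relationship_id,label,likert
frontline provider <-> consultant,high,3.85
ancillary staff <-> consultant,high,2.23
nurse <-> consultant,high,4.46
frontline provider <-> ancillary staff,high,4.08
ancillary staff <-> nurse,high,3.46
support staff <-> nurse,high,3.15
frontline provider <-> neonatologist,low,3.15
ancillary staff <-> support staff,low,2.07
nurse <-> fellow,low,3.07
frontline provider <-> fellow,low,2.84
ancillary staff <-> fellow,low,3.07
support staff <-> fellow,low,1.69
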