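((((((Dmel:0.0833,(Dsim:0.0333,Dsec:0.0333):0.05):0.1334,(Dyak:0.1667,Dere:0.1667):0.05):0.2,Dana:0.4167):0.1666,(Dpse:0.0333,Dper:0.0333):0.55):0.0834,Dwil:0.6667):0.3333,((Dmoj:0.5,Dvir:0.5):0.1667,Dgri:0.6667):0.3333);
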