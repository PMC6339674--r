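item_id,slope,b1,b2,b3,b4,n_categories,reverse_coded
ex01,3.2,-2.1,-1.2,-0.4,0.5,5,FALSE
ex02,2.6,-1.8,-0.9,0.1,0.9,5,FALSE
ex03,4.1,-2.4,-1.5,-0.7,0.2,5,TRUE
ex04,2.9,-1.3,-0.6,0.3,1.1,5,FALSE
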