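>P02754 beta-lactoglobulin synthetic ortholog [Bos taurus]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWYSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENKVLVLDTDYKKYLL
FCMENSAEPEQSLVCQCLVRTPEVDDEALEKFDKALKALPMHIRLSFNPTQLEEQCHI
>BLG_BOSIN_SYN beta-lactoglobulin synthetic ortholog [Bos indicus]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWYSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNDNKVLVLDTDYKKYLL
FCMENSAEPEQSLVCQCLVRTPEVDDEALEKFDKALKALPMHIRLSFNPTQLEEQCHI
>L8J1Z0 beta-lactoglobulin synthetic ortholog [Bos grunniens/mutus]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWYSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENKVLVLDTDYKKYLL
FCMENSAEPEQSLVCQCLVRTPEVDDEALEKFDKALKALPMHIRLSFNPTQLEGQCHI
>BLG_BISBI_SYN beta-lactoglobulin synthetic ortholog [Bison bison]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWYSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENKVLVLDTEYKKYLL
FCMENSAEPEQSLVCQCLVRTPEVDDEALEKFDKALKALPMHIRLSFNPTQLEEQCHI
>BLG_OVIAR_SYN beta-lactoglobulin synthetic ortholog [Ovis aries]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWHSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENKVLVLDTEYKKYLL
FCMENSAEPEQSLACQCLVRTPEVDNEALEKFDKALKALPMHIRLAFNPTQLEGQCHV
>BLG_CAPHI_SYN beta-lactoglobulin synthetic ortholog [Capra hircus]
MKCLLLALALTCGAQALIVTQTMKGLDIQKVAGTWHSLAMAASDISLLDAQSAPLRVYVE
ELKPTPEGDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENRVLVLDTEYKKYLL
FCMENSAEPEQSLACQCLVRTPEVDNEALDKFDKALKALPMHIRLAFNPTQLEGQCHV
>BLG_CEREL_SYN beta-lactoglobulin synthetic ortholog [Cervus elaphus]
MKCLLLALALTCGAQALIVTQTMKGLDVQKVAGTFYSLAMAASDISLLDAQSAPLRVYVE
ELKPTPENDLEILLQKWENGECAQKKIIAEKTKIPAVFKIDALNENKVLVLDTEYKKYLL
FCMENSAEPEQSLTCQCLVRTPEVDGEALEKFDKALKALPMHIRLAFNPTQLENQCHV
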