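jaw,tooth_class,ppd,sign
maxilla,central_incisor,1,1
maxilla,lateral_incisor,1,-1
maxilla,canine,1,1
maxilla,first_premolar,1,1
maxilla,second_premolar,1,-1
maxilla,first_molar,1,1
maxilla,second_molar,1,1
mandible,central_incisor,1,-1
mandible,lateral_incisor,1,1
mandible,canine,1,-1
mandible,first_premolar,1,-1
mandible,second_premolar,1,1
mandible,first_molar,1,1
mandible,second_molar,1,1
maxilla,central_incisor,2,1
maxilla,lateral_incisor,2,1
maxilla,canine,2,1
maxilla,first_premolar,2,1
maxilla,second_premolar,2,-1
maxilla,first_molar,2,1
maxilla,second_molar,2,1
mandible,central_incisor,2,-1
mandible,lateral_incisor,2,1
mandible,canine,2,1
mandible,first_premolar,2,1
mandible,second_premolar,2,-1
mandible,first_molar,2,1
mandible,second_molar,2,1
maxilla,central_incisor,3,1
maxilla,lateral_incisor,3,1
maxilla,canine,3,1
maxilla,first_premolar,3,1
maxilla,second_premolar,3,-1
maxilla,first_molar,3,1
maxilla,second_molar,3,1
mandible,central_incisor,3,-1
mandible,lateral_incisor,3,1
mandible,canine,3,1
mandible,first_premolar,3,1
mandible,second_premolar,3,-1
mandible,first_molar,3,1
mandible,second_molar,3,1
maxilla,central_incisor,4,1
maxilla,lateral_incisor,4,1
maxilla,canine,4,1
maxilla,first_premolar,4,1
maxilla,second_premolar,4,-1
maxilla,first_molar,4,1
maxilla,second_molar,4,-1
mandible,central_incisor,4,-1
mandible,lateral_incisor,4,-1
mandible,canine,4,1
mandible,first_premolar,4,1
mandible,second_premolar,4,-1
mandible,first_molar,4,1
mandible,second_molar,4,1
maxilla,central_incisor,5,-1
maxilla,lateral_incisor,5,1
maxilla,canine,5,1
maxilla,first_premolar,5,1
maxilla,second_premolar,5,-1
maxilla,first_molar,5,1
maxilla,second_molar,5,-1
mandible,central_incisor,5,-1
mandible,lateral_incisor,5,-1
mandible,canine,5,1
mandible,first_premolar,5,1
mandible,second_premolar,5,-1
mandible,first_molar,5,1
mandible,second_molar,5,-1
maxilla,central_incisor,6,-1
maxilla,lateral_incisor,6,1
maxilla,canine,6,1
maxilla,first_premolar,6,1
maxilla,second_premolar,6,-1
maxilla,first_molar,6,-1
maxilla,second_molar,6,-1
mandible,central_incisor,6,-1
mandible,lateral_incisor,6,-1
mandible,canine,6,1
mandible,first_premolar,6,1
mandible,second_premolar,6,-1
mandible,first_molar,6,1
mandible,second_molar,6,-1
maxilla,central_incisor,7,-1
maxilla,lateral_incisor,7,1
maxilla,canine,7,1
maxilla,first_premolar,7,1
maxilla,second_premolar,7,1
maxilla,first_molar,7,-1
maxilla,second_molar,7,-1
mandible,central_incisor,7,-1
mandible,lateral_incisor,7,1
mandible,canine,7,1
mandible,first_premolar,7,1
mandible,second_premolar,7,-1
mandible,first_molar,7,1
mandible,second_molar,7,-1
maxilla,central_incisor,8,-1
maxilla,lateral_incisor,8,1
maxilla,canine,8,1
maxilla,first_premolar,8,1
maxilla,second_premolar,8,1
maxilla,first_molar,8,-1
maxilla,second_molar,8,-1
mandible,central_incisor,8,-1
mandible,lateral_incisor,8,1
mandible,canine,8,1
mandible,first_premolar,8,1
mandible,second_premolar,8,-1
mandible,first_molar,8,1
mandible,second_molar,8,-1
maxilla,central_incisor,9,-1
maxilla,lateral_incisor,9,1
maxilla,canine,9,1
maxilla,first_premolar,9,1
maxilla,second_premolar,9,1
maxilla,first_molar,9,-1
maxilla,second_molar,9,-1
mandible,central_incisor,9,-1
mandible,lateral_incisor,9,1
mandible,canine,9,1
mandible,first_premolar,9,1
mandible,second_premolar,9,-1
mandible,first_molar,9,1
mandible,second_molar,9,-1
maxilla,central_incisor,10,-1
maxilla,lateral_incisor,10,1
maxilla,canine,10,1
maxilla,first_premolar,10,1
maxilla,second_premolar,10,1
maxilla,first_molar,10,-1
maxilla,second_molar,10,-1
mandible,central_incisor,10,-1
mandible,lateral_incisor,10,1
mandible,canine,10,1
mandible,first_premolar,10,1
mandible,second_premolar,10,-1
mandible,first_molar,10,1
mandible,second_molar,10,-1
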